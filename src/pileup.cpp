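#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// samtools mpileup read-base column grammar, shared by the counting and
// expansion entry points below. For every quality-consuming token the
// visitor receives (base, strand, qual); base is one of A,C,G,T,N,'*','>'.
// '^' consumes the following mapping-quality character, '$' is a marker,
// '+n'/'-n' indel strings are attached to the preceding observation and
// never consume a quality character.
template <typename Visitor>
static int walk_column(const char *bases, const char *quals, int nqual,
                       char ref, Visitor visit) {
  int qi = 0;
  for (const char *p = bases; *p; ++p) {
    char c = *p;
    if (c == '^') {
      if (*(p + 1)) ++p;  // mapping quality char
      continue;
    }
    if (c == '$') continue;
    if (c == '+' || c == '-') {
      ++p;
      if (!isdigit((unsigned char)*p))
        stop("malformed indel token in pileup base string");
      int len = 0;
      while (isdigit((unsigned char)*p)) { len = len * 10 + (*p - '0'); ++p; }
      for (int k = 0; k < len && *p; ++k) ++p;
      --p;  // loop increment compensates
      continue;
    }
    char base;
    char strand;
    if (c == '.') { base = ref; strand = '+'; }
    else if (c == ',') { base = ref; strand = '-'; }
    else if (c == '*') { base = '*'; strand = '+'; }
    else if (c == '>' || c == '<') { base = '>'; strand = (c == '>') ? '+' : '-'; }
    else if (isupper((unsigned char)c)) { base = c; strand = '+'; }
    else if (islower((unsigned char)c)) { base = toupper((unsigned char)c); strand = '-'; }
    else stop("unexpected character '%s' in pileup base string",
              std::string(1, c).c_str());
    if (qi >= nqual)
      stop("pileup base/quality length mismatch: more observations than quality characters");
    int qual = (unsigned char)quals[qi] - 33;
    ++qi;
    visit(base, strand, qual);
  }
  return qi;
}

static int base_index(char b) {
  switch (b) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

// Per-column base tallies after the base-quality filter. Returns a matrix
// with one row per column and columns:
//  A_plus A_minus C_plus C_minus G_plus G_minus T_plus T_minus
//  qual_A qual_C qual_G qual_T (sums over counted reads)
//  counted (quality-passing A/C/G/T observations) obs (all observations)
// [[Rcpp::export(name = ".pileupBaseCounts")]]
NumericMatrix pileup_base_counts(CharacterVector bases, CharacterVector quals,
                                 CharacterVector ref, int min_qual) {
  int n = bases.size();
  if (quals.size() != n || ref.size() != n)
    stop("bases, quals and ref must have equal length");
  NumericMatrix out(n, 14);
  for (int i = 0; i < n; ++i) {
    const char *b = CHAR(STRING_ELT(bases, i));
    const char *q = CHAR(STRING_ELT(quals, i));
    char r = toupper((unsigned char)*CHAR(STRING_ELT(ref, i)));
    double *row = &out(i, 0);
    int used = walk_column(b, q, (int)strlen(q), r,
      [&](char base, char strand, int qual) {
        out(i, 13) += 1;  // every observation, incl. '*' and N
        int bi = base_index(base);
        if (bi < 0) return;
        if (qual < min_qual) return;
        out(i, bi * 2 + (strand == '+' ? 0 : 1)) += 1;
        out(i, 8 + bi) += qual;
        out(i, 12) += 1;
      });
    if (used != (int)strlen(q))
      stop("pileup base/quality length mismatch at record %d", i + 1);
    (void)row;
  }
  return out;
}

// Expand one column into per-observation (base, strand, quality) triples.
// [[Rcpp::export(name = ".pileupExpand")]]
List pileup_expand(std::string bases, std::string quals, char ref) {
  std::vector<std::string> base_v, strand_v;
  std::vector<int> qual_v;
  int used = walk_column(bases.c_str(), quals.c_str(), (int)quals.size(),
                         (char)toupper((unsigned char)ref),
    [&](char base, char strand, int qual) {
      base_v.push_back(std::string(1, base));
      strand_v.push_back(std::string(1, strand));
      qual_v.push_back(qual);
    });
  if (used != (int)quals.size())
    stop("pileup base/quality length mismatch");
  return List::create(_["base"] = wrap(base_v), _["strand"] = wrap(strand_v),
                      _["quality"] = wrap(qual_v));
}
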