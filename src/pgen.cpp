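#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, T=3, -1 invalid.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static std::vector<int> encode_seq(const std::string &s) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[i]);
    if (b < 0) stop("invalid nucleotide '%c' (alphabet is A/C/G/T)", s[i]);
    out[i] = b;
  }
  return out;
}

struct VdjPar {
  std::vector<std::vector<int> > v_seq, j_seq, d_seq;
  std::vector<double> v_prob, j_prob, d_prob;
  NumericMatrix v_del, j_del, d_del5, d_del3; // rows: deletions 0..max, cols: segments
  std::vector<double> ins_vd, ins_dj;         // index = insertion length
  double pnt[4];
};

static VdjPar unpack_model(const List &model) {
  VdjPar p;
  CharacterVector vs = model["v_seq"], js = model["j_seq"], ds = model["d_seq"];
  for (int i = 0; i < vs.size(); ++i) p.v_seq.push_back(encode_seq(as<std::string>(vs[i])));
  for (int i = 0; i < js.size(); ++i) p.j_seq.push_back(encode_seq(as<std::string>(js[i])));
  for (int i = 0; i < ds.size(); ++i) p.d_seq.push_back(encode_seq(as<std::string>(ds[i])));
  p.v_prob = as<std::vector<double> >(model["v_prob"]);
  p.j_prob = as<std::vector<double> >(model["j_prob"]);
  p.d_prob = as<std::vector<double> >(model["d_prob"]);
  p.v_del = as<NumericMatrix>(model["v_del"]);
  p.j_del = as<NumericMatrix>(model["j_del"]);
  p.d_del5 = as<NumericMatrix>(model["d_del5"]);
  p.d_del3 = as<NumericMatrix>(model["d_del3"]);
  p.ins_vd = as<std::vector<double> >(model["ins_vd"]);
  p.ins_dj = as<std::vector<double> >(model["ins_dj"]);
  NumericVector np = model["nt_prob"];
  for (int i = 0; i < 4; ++i) p.pnt[i] = np[i];
  return p;
}

// P_GEN of a nucleotide CDR3: sum over recombination scenarios realizing the
// string, organised as a sum over (V-prefix length a) x (J-suffix length b)
// x (D placement within the middle segment).
// [[Rcpp::export(name = ".pgen_nt_cpp")]]
double pgen_nt_cpp(List model, std::string cdr3, IntegerVector v_keep, IntegerVector j_keep) {
  VdjPar par = unpack_model(model);
  std::vector<int> s = encode_seq(cdr3);
  int n = (int)s.size();
  if (n == 0) return 0.0;

  // pv[a]: total probability of (V, delV) choices whose truncated flank equals s[0..a)
  std::vector<double> pv(n + 1, 0.0), pj(n + 1, 0.0);
  for (size_t v = 0; v < par.v_seq.size(); ++v) {
    if (v_keep.size() && !v_keep[v]) continue;
    const std::vector<int> &fl = par.v_seq[v];
    int L = (int)fl.size();
    for (int dv = 0; dv < par.v_del.nrow(); ++dv) {
      double pd = par.v_del(dv, v);
      if (pd <= 0.0 || dv > L) continue;
      int a = L - dv;
      if (a > n) continue;
      bool ok = true;
      for (int i = 0; i < a; ++i) if (fl[i] != s[i]) { ok = false; break; }
      if (ok) pv[a] += par.v_prob[v] * pd;
    }
  }
  for (size_t j = 0; j < par.j_seq.size(); ++j) {
    if (j_keep.size() && !j_keep[j]) continue;
    const std::vector<int> &fl = par.j_seq[j];
    int L = (int)fl.size();
    for (int dj = 0; dj < par.j_del.nrow(); ++dj) {
      double pd = par.j_del(dj, j);
      if (pd <= 0.0 || dj > L) continue;
      int b = L - dj;
      if (b > n) continue;
      bool ok = true;
      for (int i = 0; i < b; ++i) if (fl[dj + i] != s[n - b + i]) { ok = false; break; }
      if (ok) pj[b] += par.j_prob[j] * pd;
    }
  }

  // cumulative product of insertion-nucleotide probabilities over s
  std::vector<double> cum(n + 1, 1.0);
  for (int i = 0; i < n; ++i) cum[i + 1] = cum[i] * par.pnt[s[i]];
  int max_ivd = (int)par.ins_vd.size() - 1, max_idj = (int)par.ins_dj.size() - 1;

  double total = 0.0;
  for (int a = 0; a <= n; ++a) {
    if (pv[a] <= 0.0) continue;
    for (int b = 0; a + b <= n; ++b) {
      if (pj[b] <= 0.0) continue;
      int mlen = n - a - b;
      double mid = 0.0;
      for (size_t d = 0; d < par.d_seq.size(); ++d) {
        const std::vector<int> &dseq = par.d_seq[d];
        int LD = (int)dseq.size();
        for (int d5 = 0; d5 < par.d_del5.nrow(); ++d5) {
          double p5 = par.d_del5(d5, d);
          if (p5 <= 0.0) continue;
          for (int d3 = 0; d3 < par.d_del3.nrow(); ++d3) {
            double p3 = par.d_del3(d3, d);
            if (p3 <= 0.0 || d5 + d3 > LD) continue;
            int dlen = LD - d5 - d3;
            if (dlen > mlen) continue;
            for (int p = 0; p <= mlen - dlen; ++p) {
              int q = mlen - dlen - p;
              if (p > max_ivd || q > max_idj) continue;
              double pins = par.ins_vd[p] * par.ins_dj[q];
              if (pins <= 0.0) continue;
              bool ok = true;
              for (int i = 0; i < dlen; ++i)
                if (dseq[d5 + i] != s[a + p + i]) { ok = false; break; }
              if (!ok) continue;
              double insw = (cum[a + p] / cum[a]) * (cum[n - b] / cum[a + p + dlen]);
              mid += par.d_prob[d] * p5 * p3 * pins * insw;
            }
          }
        }
      }
      total += pv[a] * pj[b] * mid;
    }
  }
  return total;
}

// P_GEN of an amino-acid CDR3: marginalizes all synonymous nucleotide codings
// codon by codon. `aa` is 0-based amino-acid indices into the same ordering
// used to build `gencode` (length 64, codon index b1*16+b2*4+b3 -> aa index,
// -1 for stop).
// [[Rcpp::export(name = ".pgen_aa_cpp")]]
double pgen_aa_cpp(List model, IntegerVector aa, IntegerVector gencode,
                   IntegerVector v_keep, IntegerVector j_keep) {
  VdjPar par = unpack_model(model);
  int L = aa.size();
  int n = 3 * L;
  if (L == 0) return 0.0;
  int naa = 0;
  for (int c = 0; c < 64; ++c) if (gencode[c] + 1 > naa) naa = gencode[c] + 1;

  // w[aa][pattern]: sum over codons compatible with the pattern (base fixed, 4 = free)
  // translating to aa, weighted by insertion-nucleotide probabilities at free positions.
  std::vector<std::vector<double> > w(naa, std::vector<double>(125, 0.0));
  for (int c = 0; c < 64; ++c) {
    int a = gencode[c];
    if (a < 0) continue;
    int b1 = c / 16, b2 = (c / 4) % 4, b3 = c % 4;
    for (int mask = 0; mask < 8; ++mask) {
      int p1 = (mask & 4) ? 4 : b1, p2 = (mask & 2) ? 4 : b2, p3 = (mask & 1) ? 4 : b3;
      double wt = 1.0;
      if (mask & 4) wt *= par.pnt[b1];
      if (mask & 2) wt *= par.pnt[b2];
      if (mask & 1) wt *= par.pnt[b3];
      w[a][p1 * 25 + p2 * 5 + p3] += wt;
    }
  }

  int max_ivd = (int)par.ins_vd.size() - 1, max_idj = (int)par.ins_dj.size() - 1;
  double total = 0.0;
  std::vector<int> tmpl(n);

  for (size_t v = 0; v < par.v_seq.size(); ++v) {
    if (v_keep.size() && !v_keep[v]) continue;
    const std::vector<int> &vfl = par.v_seq[v];
    int LV = (int)vfl.size();
    for (int dv = 0; dv < par.v_del.nrow(); ++dv) {
      double pvw = par.v_del(dv, v);
      if (pvw <= 0.0 || dv > LV) continue;
      int a = LV - dv;
      if (a > n) continue;
      pvw *= par.v_prob[v];
      for (size_t j = 0; j < par.j_seq.size(); ++j) {
        if (j_keep.size() && !j_keep[j]) continue;
        const std::vector<int> &jfl = par.j_seq[j];
        int LJ = (int)jfl.size();
        for (int dj = 0; dj < par.j_del.nrow(); ++dj) {
          double pjw = par.j_del(dj, j);
          if (pjw <= 0.0 || dj > LJ) continue;
          int b = LJ - dj;
          if (a + b > n) continue;
          double pvj = pvw * par.j_prob[j] * pjw;

          // prefix/suffix fixed portions of the template
          for (int i = 0; i < a; ++i) tmpl[i] = vfl[i];
          for (int i = 0; i < b; ++i) tmpl[n - b + i] = jfl[dj + i];

          // product over codons entirely inside prefix / suffix
          int n_pre = a / 3;                 // codons fully fixed by prefix
          int s0 = n - b;
          int cs = (s0 + 2) / 3;             // first codon fully in suffix
          double pre = 1.0;
          for (int i = 0; i < n_pre && pre > 0.0; ++i) {
            int pat = tmpl[3 * i] * 25 + tmpl[3 * i + 1] * 5 + tmpl[3 * i + 2];
            pre *= w[aa[i]][pat];
          }
          if (pre <= 0.0) continue;
          double suf = 1.0;
          for (int i = cs; i < L && suf > 0.0; ++i) {
            int pat = tmpl[3 * i] * 25 + tmpl[3 * i + 1] * 5 + tmpl[3 * i + 2];
            suf *= w[aa[i]][pat];
          }
          if (suf <= 0.0) continue;

          int mlen = n - a - b;
          double mid_total = 0.0;
          for (size_t d = 0; d < par.d_seq.size(); ++d) {
            const std::vector<int> &dseq = par.d_seq[d];
            int LD = (int)dseq.size();
            for (int d5 = 0; d5 < par.d_del5.nrow(); ++d5) {
              double p5 = par.d_del5(d5, d);
              if (p5 <= 0.0) continue;
              for (int d3 = 0; d3 < par.d_del3.nrow(); ++d3) {
                double p3 = par.d_del3(d3, d);
                if (p3 <= 0.0 || d5 + d3 > LD) continue;
                int dlen = LD - d5 - d3;
                if (dlen > mlen) continue;
                for (int p = 0; p <= mlen - dlen; ++p) {
                  int q = mlen - dlen - p;
                  if (p > max_ivd || q > max_idj) continue;
                  double pins = par.ins_vd[p] * par.ins_dj[q];
                  if (pins <= 0.0) continue;
                  // middle codons (possibly overlapping prefix/suffix boundaries)
                  double midw = 1.0;
                  for (int ci = n_pre; ci < cs && midw > 0.0; ++ci) {
                    int pat = 0;
                    for (int k = 0; k < 3; ++k) {
                      int pos = 3 * ci + k, bb;
                      if (pos < a) bb = tmpl[pos];
                      else if (pos >= s0) bb = tmpl[pos];
                      else {
                        int off = pos - a - p;
                        bb = (off >= 0 && off < dlen) ? dseq[d5 + off] : 4;
                      }
                      pat = pat * 5 + bb;
                    }
                    midw *= w[aa[ci]][pat];
                  }
                  if (midw > 0.0)
                    mid_total += par.d_prob[d] * p5 * p3 * pins * midw;
                }
              }
            }
          }
          total += pvj * pre * suf * mid_total;
        }
      }
    }
  }
  return total;
}

// Position (1-based) of the first occurrence of `pattern` in each read with at
// most `max_mm` mismatches; 0 when absent.
// [[Rcpp::export(name = ".find_approx_cpp")]]
IntegerVector find_approx_cpp(CharacterVector reads, std::string pattern, int max_mm) {
  int n = reads.size(), plen = (int)pattern.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    int rlen = (int)strlen(r);
    int hit = 0;
    for (int pos = 0; pos + plen <= rlen; ++pos) {
      int mm = 0;
      for (int k = 0; k < plen; ++k) {
        if (r[pos + k] != pattern[k]) { if (++mm > max_mm) break; }
      }
      if (mm <= max_mm) { hit = pos + 1; break; }
    }
    out[i] = hit;
  }
  return out;
}

// Number of mismatches between s[start..start+k) and pattern[0..k); -1 if s too short.
// [[Rcpp::export(name = ".count_mm_at_cpp")]]
IntegerVector count_mm_at_cpp(CharacterVector strings, std::string pattern,
                              IntegerVector start) {
  int n = strings.size(), k = (int)pattern.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(strings, i));
    int rlen = (int)strlen(r), s0 = start[i] - 1;
    if (s0 < 0 || s0 + k > rlen) { out[i] = -1; continue; }
    int mm = 0;
    for (int j = 0; j < k; ++j) if (r[s0 + j] != pattern[j]) ++mm;
    out[i] = mm;
  }
  return out;
}

// Best-matching flank per string. For prefixes (suffix = false): the longest
// k <= len(flank) with <= max_mm mismatches between string[0..k) and flank[0..k),
// requiring k >= min_len. For suffixes: compares string tails against flank tails
// (flank truncated from its 5' end). Returns, per string: segment index (1-based,
// 0 = none), match length, mismatches; ties broken by longer match, fewer
// mismatches, then segment order.
// [[Rcpp::export(name = ".best_flank_cpp")]]
List best_flank_cpp(CharacterVector strings, CharacterVector flanks,
                    int min_len, int max_mm, bool suffix) {
  int n = strings.size(), nf = flanks.size();
  IntegerVector seg(n), mlen(n), mm_out(n);
  std::vector<std::string> fl(nf);
  for (int f = 0; f < nf; ++f) fl[f] = as<std::string>(flanks[f]);
  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(strings, i));
    int rlen = (int)strlen(r);
    int best_f = 0, best_k = -1, best_mm = 0;
    for (int f = 0; f < nf; ++f) {
      int L = (int)fl[f].size();
      // longest k with <= max_mm mismatches
      int good_k = 0, good_mm = 0, mm = 0;
      int kmax = L < rlen ? L : rlen;
      for (int k = 1; k <= kmax; ++k) {
        char sc, fc;
        if (!suffix) { sc = r[k - 1]; fc = fl[f][k - 1]; }
        else { sc = r[rlen - k]; fc = fl[f][L - k]; }
        if (sc != fc) ++mm;
        if (mm <= max_mm) { good_k = k; good_mm = mm; }
      }
      if (good_k >= min_len) {
        if (good_k > best_k || (good_k == best_k && good_mm < best_mm)) {
          best_f = f + 1; best_k = good_k; best_mm = good_mm;
        }
      }
    }
    seg[i] = best_f;
    mlen[i] = best_k < 0 ? 0 : best_k;
    mm_out[i] = best_f ? best_mm : 0;
  }
  return List::create(_["segment"] = seg, _["match_len"] = mlen, _["mismatches"] = mm_out);
}

// Pairwise Hamming distance between equal-length strings a[i], b[i].
// [[Rcpp::export(name = ".hamming_cpp")]]
IntegerVector hamming_cpp(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *x = CHAR(STRING_ELT(a, i)), *y = CHAR(STRING_ELT(b, i));
    if (strlen(x) != strlen(y)) stop("strings of unequal length");
    int d = 0;
    for (const char *p = x, *q = y; *p; ++p, ++q) if (*p != *q) ++d;
    out[i] = d;
  }
  return out;
}
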