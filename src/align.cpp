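// Semi-global affine-gap alignment (Gotoh): the query (contig) is aligned
// end-to-end, the reference window has free end gaps. Returns a CIGAR with
// M/I/D ops and the 0-based reference start. Quadratic time with a full
// byte traceback matrix, so intended for windows up to a few kbp; larger
// inputs go through the minimap2 backend.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_align_semiglobal(std::string query, std::string ref,
                          int match = 2, int mismatch = -8,
                          int gap_open = -16, int gap_ext = -1) {
  const int n = (int)query.size(), m = (int)ref.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double)(n + 1) * (m + 1) > 4e8)
    stop("sequences too long for the built-in aligner");
  const long W = m + 1;
  const int NEG = -1000000000;
  // rolling score rows; full traceback matrix (1 byte per cell):
  // bits 0-1 H-source (0 diag, 1 E, 2 F); bit 2 E-extend; bit 3 F-extend
  std::vector<int> Hp(W), Ep(W), Fp(W), Hc(W), Ec(W), Fc(W);
  std::vector<uint8_t> tb((long)(n + 1) * W, 0);
  for (int j = 0; j <= m; ++j) { // free leading reference
    Hp[j] = 0; Ep[j] = NEG; Fp[j] = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    long r = (long)i * W;
    Hc[0] = gap_open + gap_ext * (i - 1);
    Ec[0] = NEG;
    Fc[0] = std::max(Hp[0] + gap_open, Fp[0] + gap_ext);
    for (int j = 1; j <= m; ++j) {
      int e_open = Hc[j - 1] + gap_open;
      int e_ext  = Ec[j - 1] + gap_ext;
      Ec[j] = std::max(e_open, e_ext);
      int f_open = Hp[j] + gap_open;
      int f_ext  = Fp[j] + gap_ext;
      Fc[j] = std::max(f_open, f_ext);
      int diag = Hp[j - 1] + (query[i - 1] == ref[j - 1] ? match : mismatch);
      int best = diag; uint8_t code = 0;
      if (Ec[j] > best) { best = Ec[j]; code = 1; }
      if (Fc[j] > best) { best = Fc[j]; code = 2; }
      if (e_ext >= e_open) code |= 4;
      if (f_ext >= f_open) code |= 8;
      Hc[j] = best;
      tb[r + j] = code;
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  // best end in last row (trailing reference free); Hp holds row n after swap
  int jend = 0, best = NEG;
  for (int j = 0; j <= m; ++j)
    if (Hp[j] > best) { best = Hp[j]; jend = j; }

  // traceback
  std::string ops;
  int i = n, j = jend, state = 0; // 0=H, 1=E(del), 2=F(ins)
  while (i > 0) {
    long r = (long)i * W;
    if (j == 0) { ops += 'I'; --i; continue; }
    uint8_t c = tb[r + j];
    if (state == 0) {
      int src = c & 3;
      if (src == 0) { ops += 'M'; --i; --j; }
      else state = src;
    } else if (state == 1) {
      ops += 'D';
      if (!(c & 4)) state = 0;
      --j;
    } else {
      ops += 'I';
      if (!(c & 8)) state = 0;
      --i;
    }
  }
  int ref_start = j;
  // compress reversed op string into CIGAR
  std::string cigar;
  for (long p2 = (long)ops.size() - 1; p2 >= 0;) {
    char op = ops[p2];
    long q = p2;
    while (q >= 0 && ops[q] == op) --q;
    cigar += std::to_string(p2 - q);
    cigar += op;
    p2 = q;
  }
  return List::create(_["ref_start"] = ref_start, _["cigar"] = cigar,
                      _["score"] = best);
}
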