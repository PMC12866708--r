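#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive normalized cross-correlation block matching between two frames.
// Blocks are tiled with a margin of `search` px so every candidate patch lies
// inside the frame. Returns integer+parabolic sub-pixel displacement per block.
// Ties on the correlation surface break toward smaller displacement magnitude,
// then lexicographically (row offset, col offset).
// [[Rcpp::export]]
List bm_block_match(NumericMatrix a, NumericMatrix b, int block, int search,
                    double texture_floor) {
  if (a.nrow() != b.nrow() || a.ncol() != b.ncol())
    stop("frames must have identical dimensions");
  if (block < 2 || search < 1) stop("block >= 2 and search >= 1 required");
  int nr = a.nrow(), nc = a.ncol();
  std::vector<int> r0s, c0s;
  for (int r0 = search; r0 + block + search <= nr; r0 += block) r0s.push_back(r0);
  for (int c0 = search; c0 + block + search <= nc; c0 += block) c0s.push_back(c0);
  int nbr = (int)r0s.size(), nbc = (int)c0s.size();
  if (nbr == 0 || nbc == 0)
    stop("frame too small for the requested block and search sizes");
  NumericMatrix dy(nbr, nbc), dx(nbr, nbc), score(nbr, nbc);
  LogicalMatrix valid(nbr, nbc);
  IntegerVector row0(nbr), col0(nbc);
  for (int i = 0; i < nbr; i++) row0[i] = r0s[i];
  for (int j = 0; j < nbc; j++) col0[j] = c0s[j];
  int S = 2 * search + 1;
  std::vector<double> ncc((size_t)S * S);
  double n = (double)block * block;
  const double eps = 1e-12;

  for (int bi = 0; bi < nbr; bi++) {
    for (int bj = 0; bj < nbc; bj++) {
      int r0 = r0s[bi], c0 = c0s[bj];
      double sa = 0, saa = 0;
      for (int r = 0; r < block; r++)
        for (int c = 0; c < block; c++) {
          double v = a(r0 + r, c0 + c);
          sa += v; saa += v * v;
        }
      double va = saa - sa * sa / n;
      if (va / n < texture_floor || va <= 0) {
        valid(bi, bj) = false;
        dy(bi, bj) = NA_REAL; dx(bi, bj) = NA_REAL; score(bi, bj) = NA_REAL;
        continue;
      }
      double best = -2.0;
      int bu = 0, bv = 0;
      bool any = false;
      for (int u = -search; u <= search; u++) {
        for (int v = -search; v <= search; v++) {
          double sb = 0, sbb = 0, sab = 0;
          for (int r = 0; r < block; r++) {
            int ar = r0 + r, br = r0 + r + u;
            for (int c = 0; c < block; c++) {
              double av = a(ar, c0 + c), bw = b(br, c0 + c + v);
              sb += bw; sbb += bw * bw; sab += av * bw;
            }
          }
          double vb = sbb - sb * sb / n;
          double val;
          if (vb <= 0) val = -2.0;
          else {
            val = (sab - sa * sb / n) / std::sqrt(va * vb);
            any = true;
          }
          ncc[(size_t)(u + search) * S + (v + search)] = val;
          bool take = false;
          if (val > best + eps) take = true;
          else if (val > best - eps && val > -2.0) {
            int mag = u * u + v * v, bmag = bu * bu + bv * bv;
            if (mag < bmag) take = true;
            else if (mag == bmag && (u < bu || (u == bu && v < bv))) take = true;
          }
          if (take) { best = val; bu = u; bv = v; }
        }
      }
      if (!any) {
        valid(bi, bj) = false;
        dy(bi, bj) = NA_REAL; dx(bi, bj) = NA_REAL; score(bi, bj) = NA_REAL;
        continue;
      }
      double subu = 0, subv = 0;
      // perfect matches stay integer; parabolic refinement otherwise
      if (best < 1.0 - 1e-9) {
        if (bu > -search && bu < search) {
          double cm = ncc[(size_t)(bu - 1 + search) * S + (bv + search)];
          double cc = ncc[(size_t)(bu + search) * S + (bv + search)];
          double cp = ncc[(size_t)(bu + 1 + search) * S + (bv + search)];
          double den = cm - 2 * cc + cp;
          if (den < -1e-15 && cm > -2.0 && cp > -2.0) {
            subu = 0.5 * (cm - cp) / den;
            if (subu > 0.5) subu = 0.5;
            if (subu < -0.5) subu = -0.5;
          }
        }
        if (bv > -search && bv < search) {
          double cm = ncc[(size_t)(bu + search) * S + (bv - 1 + search)];
          double cc = ncc[(size_t)(bu + search) * S + (bv + search)];
          double cp = ncc[(size_t)(bu + search) * S + (bv + 1 + search)];
          double den = cm - 2 * cc + cp;
          if (den < -1e-15 && cm > -2.0 && cp > -2.0) {
            subv = 0.5 * (cm - cp) / den;
            if (subv > 0.5) subv = 0.5;
            if (subv < -0.5) subv = -0.5;
          }
        }
      }
      valid(bi, bj) = true;
      dy(bi, bj) = bu + subu;
      dx(bi, bj) = bv + subv;
      score(bi, bj) = best;
    }
  }
  return List::create(_["dy_px"] = dy, _["dx_px"] = dx, _["ncc"] = score,
                      _["valid"] = valid, _["row0"] = row0, _["col0"] = col0,
                      _["block_px"] = block, _["search_px"] = search);
}
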