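#include <Rcpp.h>
using namespace Rcpp;

// 3D non-local means over a rows x cols x n_echo magnitude stack.
// Patches extend prs voxels spatially and pre echoes along the echo axis;
// the search window is spatial only (srs voxels). Patch distances are
// Gaussian-kernel-weighted mean squared differences, with the kernel
// separable: std a2 on the two spatial offsets, std a1 on the echo offset.
// Patches are clipped at borders and the kernel renormalized over offsets
// valid for both patch centers. The self weight is the maximum weight of
// the other candidates in the window (standard practice, avoids
// self-domination). h is the per-echo smoothing bandwidth.

static inline int idx3(int i, int j, int k, int nr, int nc) {
  return i + j * nr + k * nr * nc;
}

// offs[te] is the expected patch distance between two noise realizations of
// the same underlying patch (2 * sigma^2 per echo); subtracting it before
// the exponential makes same-structure weights ~1 and leaves h to control
// edge tolerance.
// [[Rcpp::export]]
NumericVector nlm3d_cpp(NumericVector stack, int nr, int nc, int ne,
                        int prs, int pre, int srs,
                        double a1, double a2, NumericVector h,
                        NumericVector offs) {
  if ((int)h.size() != ne) stop("h must have one value per echo");
  if ((int)offs.size() != ne) stop("offs must have one value per echo");
  NumericVector out(stack.size());
  const double *v = stack.begin();
  double *o = out.begin();

  // precompute separable kernel factors
  std::vector<double> ks(2 * prs + 1), ke(2 * pre + 1);
  for (int d = -prs; d <= prs; ++d)
    ks[d + prs] = std::exp(-0.5 * d * d / (a2 * a2));
  for (int d = -pre; d <= pre; ++d)
    ke[d + pre] = std::exp(-0.5 * d * d / (a1 * a1));

  for (int te = 0; te < ne; ++te) {
    const double h2 = h[te] * h[te];
    const double off = offs[te];
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double wsum = 0.0, acc = 0.0, wmax = 0.0;
        for (int sj = std::max(0, j - srs); sj <= std::min(nc - 1, j + srs); ++sj) {
          for (int si = std::max(0, i - srs); si <= std::min(nr - 1, i + srs); ++si) {
            if (si == i && sj == j) continue;
            // kernel-weighted patch distance, clipped at borders for both
            double num = 0.0, den = 0.0;
            for (int dz = -pre; dz <= pre; ++dz) {
              int tz = te + dz;
              if (tz < 0 || tz >= ne) continue;
              const double kz = ke[dz + pre];
              for (int dy = -prs; dy <= prs; ++dy) {
                int y1 = j + dy, y2 = sj + dy;
                if (y1 < 0 || y1 >= nc || y2 < 0 || y2 >= nc) continue;
                const double kyz = kz * ks[dy + prs];
                for (int dx = -prs; dx <= prs; ++dx) {
                  int x1 = i + dx, x2 = si + dx;
                  if (x1 < 0 || x1 >= nr || x2 < 0 || x2 >= nr) continue;
                  const double k = kyz * ks[dx + prs];
                  const double diff = v[idx3(x1, y1, tz, nr, nc)] -
                                      v[idx3(x2, y2, tz, nr, nc)];
                  num += k * diff * diff;
                  den += k;
                }
              }
            }
            double d = (den > 0.0) ? num / den : 0.0;
            d = (d > off) ? d - off : 0.0;
            const double w = std::exp(-d / h2);
            if (w > wmax) wmax = w;
            wsum += w;
            acc += w * v[idx3(si, sj, te, nr, nc)];
          }
        }
        const double wself = (wmax > 0.0) ? wmax : 1.0;
        wsum += wself;
        acc += wself * v[idx3(i, j, te, nr, nc)];
        o[idx3(i, j, te, nr, nc)] = acc / wsum;
      }
    }
  }
  return out;
}
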