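#include <Rcpp.h>
using namespace Rcpp;

// Conservative flux-form explicit finite differences for
//   dK/dt = div( D(x) grad K ) + src(x) - sink(x) * K
// on a regular square grid with zero-flux (mirror) boundaries and
// harmonic-mean interface diffusivities. Substep size obeys the diffusion
// stability bound dx^2/(4 max D) (with a 0.9 safety factor) and an accuracy
// cap sink*dt <= 1e-3 so that first-order decay is resolved to <0.1% over a
// half-life by the explicit scheme.

static inline double face_d(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

// One substep over the whole grid. `dv` holds the vertical-face conductances
// (between rows i and i+1, length (nr-1) per column), `dh` the horizontal
// ones; both are pre-multiplied by 1/dx^2 so flux sums are rates directly.
static double substep(const double* K, double* out, const double* dv,
                      const double* dh, const double* src, const double* sink,
                      int nr, int nc, double dt, double* pmax) {
  double maxchange = 0.0, kmax = 0.0;
  for (int j = 0; j < nc; ++j) {
    const double* kc = K + (size_t)j * nr;
    double* oc = out + (size_t)j * nr;
    const double* dvc = dv + (size_t)j * (nr - 1);
    const double* sc = src + (size_t)j * nr;
    const double* snk = sink + (size_t)j * nr;
    const double* kl = (j > 0) ? kc - nr : NULL;
    const double* kr = (j < nc - 1) ? kc + nr : NULL;
    const double* dhl = (j > 0) ? dh + (size_t)(j - 1) * nr : NULL;
    const double* dhr = (j < nc - 1) ? dh + (size_t)j * nr : NULL;
    for (int i = 0; i < nr; ++i) {
      const double k0 = kc[i];
      double flux = 0.0;
      if (i > 0)      flux += dvc[i - 1] * (kc[i - 1] - k0);
      if (i < nr - 1) flux += dvc[i] * (kc[i + 1] - k0);
      if (kl)         flux += dhl[i] * (kl[i] - k0);
      if (kr)         flux += dhr[i] * (kr[i] - k0);
      double v = k0 + dt * (flux + sc[i] - snk[i] * k0);
      if (v < 0.0) {
        if (v > -1e-9 * (k0 > 1.0 ? k0 : 1.0)) v = 0.0;
        else stop("field update produced a negative value (%g) at (%d,%d)",
                  v, i + 1, j + 1);
      }
      const double ch = v - k0;
      if (ch > maxchange) maxchange = ch;
      else if (-ch > maxchange) maxchange = -ch;
      if (v > kmax) kmax = v;
      oc[i] = v;
    }
  }
  *pmax = kmax;
  return maxchange;
}

// [[Rcpp::export(name = ".fd_substeps_cpp")]]
List fd_substeps_cpp(NumericMatrix K, NumericMatrix D, NumericMatrix src,
                     NumericMatrix sink, double dx, double dt_total,
                     bool relax, double tol, int max_steps) {
  const int nr = K.nrow(), nc = K.ncol();
  double dmax = 0.0, smax = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (D(i, j) > dmax) dmax = D(i, j);
      if (sink(i, j) > smax) smax = sink(i, j);
    }
  double dt_sub = R_PosInf;
  if (dmax > 0.0) dt_sub = 0.9 * dx * dx / (4.0 * dmax);
  if (smax > 0.0) dt_sub = std::min(dt_sub, 1e-3 / smax);

  // precompute face conductances (harmonic mean / dx^2), fixed over substeps
  const double inv_dx2 = 1.0 / (dx * dx);
  std::vector<double> dv((size_t)(nr - 1) * nc), dh((size_t)nr * (nc - 1));
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr - 1; ++i)
      dv[(size_t)j * (nr - 1) + i] = face_d(D(i, j), D(i + 1, j)) * inv_dx2;
  for (int j = 0; j < nc - 1; ++j)
    for (int i = 0; i < nr; ++i)
      dh[(size_t)j * nr + i] = face_d(D(i, j), D(i, j + 1)) * inv_dx2;

  NumericMatrix a = clone(K), b(nr, nc);
  double* pa = a.begin();
  double* pb = b.begin();
  double kmax = 0.0;
  int steps;
  bool converged = false;
  if (!relax) {
    if (!R_FINITE(dt_sub) || dt_sub > dt_total) dt_sub = dt_total;
    steps = (int)std::ceil(dt_total / dt_sub - 1e-12);
    if (steps < 1) steps = 1;
    dt_sub = dt_total / steps;
    for (int s = 0; s < steps; ++s) {
      substep(pa, pb, dv.data(), dh.data(), src.begin(), sink.begin(),
              nr, nc, dt_sub, &kmax);
      std::swap(pa, pb);
    }
  } else {
    if (!R_FINITE(dt_sub)) stop("relaxation requires diffusion or a sink");
    steps = 0;
    while (steps < max_steps) {
      const double ch = substep(pa, pb, dv.data(), dh.data(), src.begin(),
                                sink.begin(), nr, nc, dt_sub, &kmax);
      std::swap(pa, pb);
      ++steps;
      if (ch <= tol * (kmax > 0.0 ? kmax : 1.0)) { converged = true; break; }
    }
  }
  NumericMatrix res = (pa == a.begin()) ? a : b;
  for (double* p = res.begin(); p != res.end(); ++p)
    if (!R_FINITE(*p)) stop("field update produced a non-finite value");
  return List::create(_["values"] = res, _["steps"] = steps,
                      _["dt_sub"] = dt_sub, _["converged"] = converged,
                      _["max"] = kmax);
}

// Daughter placement: scan neighbourhood rings of the drawn shape outward
// from the parent; at the first order containing a free site, return one free
// site uniformly at random. 1-based coordinates; c(NA, NA) if every ring up
// to max_order is fully occupied.

// [[Rcpp::export(name = ".place_daughter_cpp")]]
IntegerVector place_daughter_cpp(IntegerMatrix occ, int pr, int pc,
                                 int shape, int max_order) {
  const int nr = occ.nrow(), nc = occ.ncol();
  if (pr < 1 || pr > nr || pc < 1 || pc > nc)
    stop("parent coordinate off-lattice");
  std::vector<int> fr, fc;
  fr.reserve(64); fc.reserve(64);
  for (int k = 1; k <= max_order; ++k) {
    fr.clear(); fc.clear();
    if (shape == 0) {                       // Moore ring, Chebyshev radius k
      for (int dc = -k; dc <= k; ++dc) {
        for (int s = -1; s <= 1; s += 2) {  // top and bottom rows
          const int r = pr + s * k, c = pc + dc;
          if (r >= 1 && r <= nr && c >= 1 && c <= nc && occ(r - 1, c - 1) == 0) {
            fr.push_back(r); fc.push_back(c);
          }
        }
      }
      for (int dr = -k + 1; dr <= k - 1; ++dr) {
        for (int s = -1; s <= 1; s += 2) {  // left and right columns
          const int r = pr + dr, c = pc + s * k;
          if (r >= 1 && r <= nr && c >= 1 && c <= nc && occ(r - 1, c - 1) == 0) {
            fr.push_back(r); fc.push_back(c);
          }
        }
      }
    } else {                                // von Neumann ring, Manhattan radius k
      for (int dr = -k; dr <= k; ++dr) {
        const int w = k - std::abs(dr);
        for (int s = -1; s <= 1; s += 2) {
          if (w == 0 && s == 1) continue;   // avoid double-counting dc = 0
          const int r = pr + dr, c = pc + s * w;
          if (r >= 1 && r <= nr && c >= 1 && c <= nc && occ(r - 1, c - 1) == 0) {
            fr.push_back(r); fc.push_back(c);
          }
        }
      }
    }
    const int nfree = (int)fr.size();
    if (nfree > 0) {
      int idx = (int)std::floor(unif_rand() * nfree);
      if (idx >= nfree) idx = nfree - 1;
      return IntegerVector::create(fr[idx], fc[idx]);
    }
  }
  return IntegerVector::create(NA_INTEGER, NA_INTEGER);
}
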