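#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system.
// a: sub-diagonal (a[0] ignored), b: diagonal, c: super-diagonal
// (c[n-1] ignored), d: right-hand side.
// [[Rcpp::export]]
NumericVector thomas_solve(NumericVector a, NumericVector b,
                           NumericVector c, NumericVector d) {
  int n = b.size();
  if (a.size() != n || c.size() != n || d.size() != n)
    stop("tridiagonal bands must have equal length");
  NumericVector cp(n), dp(n), x(n);
  double denom = b[0];
  if (denom == 0.0) stop("tridiagonal solve failed: zero pivot at row 1");
  cp[0] = c[0] / denom;
  dp[0] = d[0] / denom;
  for (int i = 1; i < n; ++i) {
    denom = b[i] - a[i] * cp[i - 1];
    if (denom == 0.0 || !std::isfinite(denom))
      stop("tridiagonal solve failed: degenerate pivot at row %d", i + 1);
    cp[i] = c[i] / denom;
    dp[i] = (d[i] - a[i] * dp[i - 1]) / denom;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}

// One conservative flux-corrected-transport step for
//   df/dt + (1/r^2) d(r^2 v f)/dr = 0
// on node volumes w with face areas S_face (length n-1; face i sits between
// nodes i and i+1).  Zero flux through the centre (below node 0) and the
// outer border (above node n-1).  Donor-cell low-order transport plus a
// Zalesak-limited centred antidiffusive flux: conserves sum(w*f) to
// round-off and creates no new extrema.
// [[Rcpp::export]]
NumericVector fct_advect_step(NumericVector f, NumericVector v_face,
                              double dt, NumericVector w,
                              NumericVector S_face) {
  int n = f.size();
  if (v_face.size() != n - 1 || S_face.size() != n - 1 || w.size() != n)
    stop("inconsistent grid arrays in fct_advect_step");
  NumericVector FL(n - 1), AD(n - 1), ftd(n);

  for (int i = 0; i < n - 1; ++i) {
    double vf = v_face[i];
    double donor = (vf >= 0.0) ? f[i] : f[i + 1];
    FL[i] = S_face[i] * vf * donor;
    double FH = S_face[i] * vf * 0.5 * (f[i] + f[i + 1]);
    AD[i] = FH - FL[i];
  }

  // low-order (transported-diffused) solution
  for (int i = 0; i < n; ++i) {
    double fin  = (i > 0)     ? FL[i - 1] : 0.0;
    double fout = (i < n - 1) ? FL[i]     : 0.0;
    ftd[i] = f[i] - dt * (fout - fin) / w[i];
  }

  // Zalesak limiter bounds from old and transported values
  NumericVector fmax(n), fmin(n);
  for (int i = 0; i < n; ++i) {
    double lo = std::min(f[i], ftd[i]);
    double hi = std::max(f[i], ftd[i]);
    if (i > 0) {
      lo = std::min(lo, std::min(f[i - 1], ftd[i - 1]));
      hi = std::max(hi, std::max(f[i - 1], ftd[i - 1]));
    }
    if (i < n - 1) {
      lo = std::min(lo, std::min(f[i + 1], ftd[i + 1]));
      hi = std::max(hi, std::max(f[i + 1], ftd[i + 1]));
    }
    fmin[i] = lo;
    fmax[i] = hi;
  }

  NumericVector Rp(n), Rm(n);
  for (int i = 0; i < n; ++i) {
    double Pp = 0.0, Pm = 0.0;
    if (i > 0) {
      Pp += std::max(0.0, AD[i - 1]);
      Pm += std::max(0.0, -AD[i - 1]);
    }
    if (i < n - 1) {
      Pp += std::max(0.0, -AD[i]);
      Pm += std::max(0.0, AD[i]);
    }
    double Qp = (fmax[i] - ftd[i]) * w[i] / dt;
    double Qm = (ftd[i] - fmin[i]) * w[i] / dt;
    Rp[i] = (Pp > 0.0) ? std::min(1.0, Qp / Pp) : 0.0;
    Rm[i] = (Pm > 0.0) ? std::min(1.0, Qm / Pm) : 0.0;
  }

  NumericVector Cf(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    // AD[i] > 0 moves mass from node i+1 into node i
    Cf[i] = (AD[i] >= 0.0) ? std::min(Rp[i], Rm[i + 1])
                           : std::min(Rp[i + 1], Rm[i]);
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double fin  = (i > 0)     ? Cf[i - 1] * AD[i - 1] : 0.0;
    double fout = (i < n - 1) ? Cf[i] * AD[i]         : 0.0;
    // limited antidiffusive flux convention: positive AD at face i adds to
    // node i and removes from node i+1
    out[i] = ftd[i] + dt * (fout - fin) / w[i];
  }
  return out;
}

// Crank-Nicolson step for spherical diffusion
//   df/dt = (1/r^2) d/dr ( D r^2 df/dr )
// in conservative finite-volume form on node volumes w with face areas
// S_face.  bc = 0: zero flux at the outer border; bc = 1: Dirichlet value
// bc_value at the outer node.  The centre is always a symmetry (zero-flux)
// boundary.
// [[Rcpp::export]]
NumericVector cn_diffuse_step(NumericVector f, double D, double dt,
                              NumericVector w, NumericVector S_face,
                              double dr, int bc, double bc_value) {
  int n = f.size();
  if (S_face.size() != n - 1 || w.size() != n)
    stop("inconsistent grid arrays in cn_diffuse_step");
  NumericVector a(n), b(n), c(n), d(n);
  for (int i = 0; i < n; ++i) {
    double kin  = (i > 0)     ? D * S_face[i - 1] / dr : 0.0;
    double kout = (i < n - 1) ? D * S_face[i] / dr     : 0.0;
    a[i] = -0.5 * kin;
    c[i] = -0.5 * kout;
    b[i] = w[i] / dt + 0.5 * (kin + kout);
    double expl = 0.0;
    if (i > 0)     expl -= kin  * (f[i] - f[i - 1]);
    if (i < n - 1) expl += kout * (f[i + 1] - f[i]);
    d[i] = w[i] / dt * f[i] + 0.5 * expl;
  }
  if (bc == 1) {  // Dirichlet at the outer node
    a[n - 1] = 0.0;
    c[n - 1] = 0.0;
    b[n - 1] = 1.0;
    d[n - 1] = bc_value;
  }
  return thomas_solve(a, b, c, d);
}
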