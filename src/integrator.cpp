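#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Classical fixed-step RK4 steppers for the phase model.  Fixed stepping
// (no adaptivity) keeps spike timing bit-reproducible across runs.

// Steady temperature: parameters b, A, Omega are constants and the
// modulation phase is exactly Omega * t.
//   dtheta/dt = (b - A cos(Omega t)) + (1 + A cos(Omega t)) cos(theta)
// [[Rcpp::export(name = ".rk4_steady")]]
NumericMatrix rk4_steady(double b, double A, double Omega,
                         double theta0, double dt,
                         int nstep, int stride) {
  if (dt <= 0 || nstep < 1 || stride < 1)
    stop("rk4_steady: invalid dt/nstep/stride");
  const int nrec = nstep / stride + 1;
  NumericMatrix out(nrec, 4);
  colnames(out) = CharacterVector::create("t", "theta", "F", "phi");

  double theta = theta0;
  int irec = 0;
  auto record = [&](int step) {
    const double t = step * dt;
    const double cp = std::cos(Omega * t);
    const double f1 = b - A * cp, f2 = 1.0 + A * cp;
    out(irec, 0) = t;
    out(irec, 1) = theta;
    out(irec, 2) = f1 + f2 * std::cos(theta);
    out(irec, 3) = Omega * t;
    ++irec;
  };
  auto rhs = [&](double t, double th) {
    const double cp = std::cos(Omega * t);
    return (b - A * cp) + (1.0 + A * cp) * std::cos(th);
  };

  record(0);
  for (int k = 0; k < nstep; ++k) {
    const double t = k * dt;
    const double k1 = rhs(t, theta);
    const double k2 = rhs(t + 0.5 * dt, theta + 0.5 * dt * k1);
    const double k3 = rhs(t + 0.5 * dt, theta + 0.5 * dt * k2);
    const double k4 = rhs(t + dt, theta + dt * k3);
    theta += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!std::isfinite(theta))
      stop("rk4_steady: non-finite phase at t = %f ms", (k + 1) * dt);
    if ((k + 1) % stride == 0) record(k + 1);
  }
  return out;
}

struct TanhSet {
  double b0, b1, A0, A1, Om0, Om1, C, Tbar;
};

// Coupled transient system.  State y = (theta, w, phi):
//   Teff      = T0eff + w^2
//   (b,A,Om)  = tanh forms at Teff
//   a         = a_const                    (const_a)
//             | a0 exp(alpha (w^2+T0eff))  (state-dependent width)
//   dw/dt     = a (sqrt(D) - w)
//   phi_mod   = phi (integrated: dphi/dt = Om) | Om * t (literal)
//   dtheta/dt = (b - A cos(phi_mod)) + (1 + A cos(phi_mod)) cos(theta)
// [[Rcpp::export(name = ".rk4_transition")]]
NumericMatrix rk4_transition(List pset, double D, double T0eff,
                             bool const_a, double a_const,
                             double a0, double alpha,
                             double theta0, double w0, double phi0,
                             double dt, int nstep, int stride,
                             bool literal) {
  if (dt <= 0 || nstep < 1 || stride < 1)
    stop("rk4_transition: invalid dt/nstep/stride");
  TanhSet p = {as<double>(pset["b0"]), as<double>(pset["b1"]),
               as<double>(pset["A0"]), as<double>(pset["A1"]),
               as<double>(pset["Omega0"]), as<double>(pset["Omega1"]),
               as<double>(pset["C"]), as<double>(pset["Tbar"])};
  const double sqrtD = std::sqrt(D);

  const int nrec = nstep / stride + 1;
  NumericMatrix out(nrec, 6);
  colnames(out) = CharacterVector::create("t", "theta", "F", "phi", "w",
                                          "Teff");

  double theta = theta0, w = w0, phi = phi0;
  int irec = 0;

  auto derivs = [&](double t, double th, double wv, double ph,
                    double* d) {
    const double Teff = T0eff + wv * wv;
    const double s = std::tanh(p.C * (Teff - p.Tbar));
    const double b = p.b0 - p.b1 * s;
    const double A = p.A0 + p.A1 * s;
    const double Om = p.Om0 + p.Om1 * s;
    const double a = const_a ? a_const : a0 * std::exp(alpha * Teff);
    const double phim = literal ? Om * t : ph;
    const double cp = std::cos(phim);
    d[0] = (b - A * cp) + (1.0 + A * cp) * std::cos(th);  // dtheta
    d[1] = a * (sqrtD - wv);                              // dw
    d[2] = Om;                                            // dphi
  };

  auto record = [&](int step) {
    const double t = step * dt;
    const double Teff = T0eff + w * w;
    const double s = std::tanh(p.C * (Teff - p.Tbar));
    const double b = p.b0 - p.b1 * s;
    const double A = p.A0 + p.A1 * s;
    const double Om = p.Om0 + p.Om1 * s;
    const double phim = literal ? Om * t : phi;
    const double cp = std::cos(phim);
    out(irec, 0) = t;
    out(irec, 1) = theta;
    out(irec, 2) = (b - A * cp) + (1.0 + A * cp) * std::cos(theta);
    out(irec, 3) = phim;
    out(irec, 4) = w;
    out(irec, 5) = Teff;
    ++irec;
  };

  record(0);
  double k1[3], k2[3], k3[3], k4[3];
  for (int k = 0; k < nstep; ++k) {
    const double t = k * dt;
    derivs(t, theta, w, phi, k1);
    derivs(t + 0.5 * dt, theta + 0.5 * dt * k1[0], w + 0.5 * dt * k1[1],
           phi + 0.5 * dt * k1[2], k2);
    derivs(t + 0.5 * dt, theta + 0.5 * dt * k2[0], w + 0.5 * dt * k2[1],
           phi + 0.5 * dt * k2[2], k3);
    derivs(t + dt, theta + dt * k3[0], w + dt * k3[1], phi + dt * k3[2],
           k4);
    theta += dt / 6.0 * (k1[0] + 2 * k2[0] + 2 * k3[0] + k4[0]);
    w     += dt / 6.0 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]);
    phi   += dt / 6.0 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]);
    if (!std::isfinite(theta) || !std::isfinite(w) || !std::isfinite(phi))
      stop("rk4_transition: non-finite state at t = %f ms", (k + 1) * dt);
    if ((k + 1) % stride == 0) record(k + 1);
  }
  return out;
}
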