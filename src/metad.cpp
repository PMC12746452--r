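// Overdamped Langevin propagation on analytic toy potentials, with optional
// well-tempered metadynamics biasing along one coordinate. The bias is
// maintained on a uniform grid (energy and force nodes) so per-step lookup is
// O(1); the deposited-Gaussian log is kept for FES estimation and
// convergence analysis. Units: nm, kJ/mol, ps, K.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KB = 0.008314462618; // kJ/mol/K

// form ids: 1 harmonic, 2 double-well-1d, 3 flat-1d, 4 double-funnel-2d
static inline double energyGrad(int form, const double* p, const double* x,
                                int dim, double* grad) {
  switch (form) {
  case 1: { // k, x0
    double d = x[0] - p[1];
    grad[0] = p[0] * d;
    return 0.5 * p[0] * d * d;
  }
  case 2: { // a, b, L: U = a ((x/L)^2 - 1)^2 + b (x/L)
    double u = x[0] / p[2];
    double u2 = u * u;
    grad[0] = (4.0 * p[0] * u * (u2 - 1.0) + p[1]) / p[2];
    return p[0] * (u2 - 1.0) * (u2 - 1.0) + p[1] * u;
  }
  case 3: { // lo, hi, kwall
    if (x[0] < p[0]) {
      double d = x[0] - p[0];
      grad[0] = p[2] * d;
      return 0.5 * p[2] * d * d;
    } else if (x[0] > p[1]) {
      double d = x[0] - p[1];
      grad[0] = p[2] * d;
      return 0.5 * p[2] * d * d;
    }
    grad[0] = 0.0;
    return 0.0;
  }
  case 4: { // x1,y1,d1,w1, x2,y2,d2,w2, kc
    double dx1 = x[0] - p[0], dy1 = x[1] - p[1];
    double dx2 = x[0] - p[4], dy2 = x[1] - p[5];
    double g1 = std::exp(-(dx1 * dx1 + dy1 * dy1) / (2.0 * p[3] * p[3]));
    double g2 = std::exp(-(dx2 * dx2 + dy2 * dy2) / (2.0 * p[7] * p[7]));
    double U = -p[2] * g1 - p[6] * g2 +
               0.5 * p[8] * (x[0] * x[0] + x[1] * x[1]);
    grad[0] = p[2] * g1 * dx1 / (p[3] * p[3]) +
              p[6] * g2 * dx2 / (p[7] * p[7]) + p[8] * x[0];
    grad[1] = p[2] * g1 * dy1 / (p[3] * p[3]) +
              p[6] * g2 * dy2 / (p[7] * p[7]) + p[8] * x[1];
    return U;
  }
  }
  stop("unknown potential form id");
  return 0.0;
}

struct BiasGrid {
  double lo, hi, h;
  int nnode;
  std::vector<double> V, F; // energy and minus-dV/ds at nodes

  BiasGrid(double lo_, double hi_, int nbins, NumericVector V0,
           NumericVector F0)
      : lo(lo_), hi(hi_), nnode(nbins + 1) {
    h = (hi - lo) / nbins;
    V.assign(nnode, 0.0);
    F.assign(nnode, 0.0);
    if (V0.size() == nnode)
      for (int i = 0; i < nnode; ++i) { V[i] = V0[i]; F[i] = F0[i]; }
  }
  inline double clampS(double s) const {
    if (s < lo) return lo;
    if (s > hi) return hi;
    return s;
  }
  inline double value(double s) const {
    s = clampS(s);
    int i = (int)((s - lo) / h);
    if (i >= nnode - 1) i = nnode - 2;
    double t = (s - (lo + i * h)) / h;
    return V[i] * (1.0 - t) + V[i + 1] * t;
  }
  inline double force(double s) const { // -dVbias/ds; flat outside the grid
    if (s <= lo || s >= hi) return 0.0;
    int i = (int)((s - lo) / h);
    if (i >= nnode - 1) i = nnode - 2;
    double t = (s - (lo + i * h)) / h;
    return F[i] * (1.0 - t) + F[i + 1] * t;
  }
  // add h0 * exp(-(s-c)^2 / (2 sigma^2)), truncated at 6 sigma
  void deposit(double c, double h0, double sigma) {
    double cut = 6.0 * sigma;
    int i0 = (int)std::floor((c - cut - lo) / h);
    int i1 = (int)std::ceil((c + cut - lo) / h);
    if (i0 < 0) i0 = 0;
    if (i1 > nnode - 1) i1 = nnode - 1;
    double s2 = sigma * sigma;
    for (int i = i0; i <= i1; ++i) {
      double d = (lo + i * h) - c;
      double g = h0 * std::exp(-d * d / (2.0 * s2));
      V[i] += g;
      F[i] += g * d / s2; // -d/ds of the Gaussian
    }
  }
};

// [[Rcpp::export(name = ".runLangevinCpp")]]
List runLangevinCpp(int form, NumericVector params, NumericVector x0,
                    double temperature, double friction, double dt,
                    int nsteps, int seed, bool metad, double w, double sigma,
                    double gammaFactor, int pace, int step0, int cvIndex,
                    double gridLo, double gridHi, int gridBins,
                    NumericVector biasV, NumericVector biasF,
                    int recordStride, double domainLimit) {
  int dim = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> grad(dim, 0.0);
  const double* p = params.begin();

  BiasGrid bias(gridLo, gridHi, gridBins, biasV, biasF);

  std::mt19937 rng((uint32_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  double kT = KB * temperature;
  double mob = dt / friction;                  // mobility * dt
  double noise = std::sqrt(2.0 * kT * mob);    // Euler-Maruyama amplitude

  int nrec = nsteps / recordStride + 1;
  NumericMatrix traj(nrec, 3 + dim);
  std::vector<double> centers, heights, times;
  double deltaT = (gammaFactor - 1.0) * temperature; // well-tempering DeltaT

  int irec = 0;
  for (int step = 0; step <= nsteps; ++step) {
    double U = energyGrad(form, p, x.data(), dim, grad.data());
    double s = x[cvIndex];
    double vb = metad ? bias.value(s) : 0.0;

    if (step % recordStride == 0 && irec < nrec) {
      traj(irec, 0) = (step0 + step) * dt;
      for (int d = 0; d < dim; ++d) traj(irec, 1 + d) = x[d];
      traj(irec, 1 + dim) = U;
      traj(irec, 2 + dim) = vb;
      ++irec;
    }
    if (step == nsteps) break;

    // deposit before the move, every `pace` global steps (skip global step 0)
    int gstep = step0 + step;
    // depositions outside the bias grid are skipped (never clamped: piling
    // Gaussians at the edge would build an artificial wall there)
    if (metad && pace > 0 && gstep > 0 && gstep % pace == 0 &&
        s >= bias.lo && s <= bias.hi) {
      double hdep;
      if (std::isinf(gammaFactor)) hdep = w;
      else hdep = w * std::exp(-bias.value(s) / (KB * deltaT));
      bias.deposit(s, hdep, sigma);
      centers.push_back(s);
      heights.push_back(hdep);
      times.push_back(gstep * dt);
      vb = bias.value(s);
    }

    double fb = metad ? bias.force(s) : 0.0;
    for (int d = 0; d < dim; ++d) {
      double f = -grad[d] + (d == cvIndex ? fb : 0.0);
      double xi = (temperature > 0.0) ? gauss(rng) : 0.0;
      x[d] += mob * f + noise * xi;
      if (std::abs(x[d]) > domainLimit)
        stop("trajectory diverged (|x| exceeded the domain limit); use a smaller dt");
    }
  }

  return List::create(
      _["traj"] = traj, _["centers"] = NumericVector(centers.begin(), centers.end()),
      _["heights"] = NumericVector(heights.begin(), heights.end()),
      _["times"] = NumericVector(times.begin(), times.end()),
      _["xFinal"] = NumericVector(x.begin(), x.end()),
      _["biasV"] = NumericVector(bias.V.begin(), bias.V.end()),
      _["biasF"] = NumericVector(bias.F.begin(), bias.F.end()));
}
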