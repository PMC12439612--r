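// Single-site Gibbs sampler for the bivariate animal model with
// trait 1 = milk production (linear) and trait 2 = age at first calving,
// either linear or threshold (latent liability with fixed threshold 0).
//
// Records are bivariate rows; an animal's AFC record rides on its first
// milk row when one exists.  Location effects are updated one at a time
// from full conditionals that use the observed-partition residual
// precision of each row; missing-trait residuals are augmented only for
// the inverse-Wishart residual update (a blocked draw, so the scheme
// leaves the joint posterior invariant).
//
// Randomness: a self-contained xoshiro256++ stream seeded deterministically
// from the chain seed (normals by the polar method, gammas by
// Marsaglia-Tsang), so a given seed yields a bit-identical chain while
// keeping per-draw cost low -- the sampler draws ~10^4 variates per cycle.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed into the xoshiro state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {                // (0, 1)
    return ((next() >> 11) + 0.5) * 0x1.0p-53;
  }
  double norm() {                       // Marsaglia polar
    if (have_spare) { have_spare = false; return spare; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f; have_spare = true;
    return u * f;
  }
  double gamma(double a) {              // Marsaglia-Tsang, shape a, scale 1
    if (a < 1.0) {
      double u = unif();
      return gamma(a + 1.0) * std::pow(u, 1.0 / a);
    }
    double d = a - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do { x = norm(); v = 1.0 + c * x; } while (v <= 0.0);
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
  inline double chisq(double df) { return 2.0 * gamma(0.5 * df); }
};

// lower-tail truncated standard normal: z | z <= b, robust far in the tail
static double rtnorm_below(Rng& rng, double b) {
  double lp = R::pnorm(b, 0.0, 1.0, 1, 1);       // log Phi(b)
  return R::qnorm(lp + std::log(rng.unif()), 0.0, 1.0, 1, 1);
}

// draw u ~ N(mu, sd^2) truncated to u <= 0 (cls 1) or u > 0 (cls 2)
static double rtnorm_class(Rng& rng, double mu, double sd, int cls) {
  double b = -mu / sd;                           // standardized threshold
  if (cls == 1) return mu + sd * rtnorm_below(rng, b);
  return mu - sd * rtnorm_below(rng, -b);        // reflect for upper tail
}

// G = inverse-Wishart(df, S) with density |G|^{-(df+p+1)/2} exp(-tr(S G^-1)/2),
// p = 2: draw W ~ Wishart(df, S^-1) by Bartlett, return G = W^-1.
static void riwish2(Rng& rng, double df, const double S[3], double out[3]) {
  // S = (s00, s11, s01); Sigma = S^-1, L = chol(Sigma) lower
  double det = S[0] * S[1] - S[2] * S[2];
  if (det <= 0.0 || S[0] <= 0.0) stop("inverse-Wishart scale not positive definite");
  double sg00 = S[1] / det, sg11 = S[0] / det, sg01 = -S[2] / det;
  double l00 = std::sqrt(sg00);
  double l10 = sg01 / l00;
  double l11 = std::sqrt(sg11 - l10 * l10);
  // Bartlett factor A lower-triangular
  double a00 = std::sqrt(rng.chisq(df));
  double a10 = rng.norm();
  double a11 = std::sqrt(rng.chisq(df - 1.0));
  // T = L * A  (lower), W = T T'
  double t00 = l00 * a00;
  double t10 = l10 * a00 + l11 * a10;
  double t11 = l11 * a11;
  double w00 = t00 * t00;
  double w01 = t00 * t10;
  double w11 = t10 * t10 + t11 * t11;
  double dw = w00 * w11 - w01 * w01;
  out[0] = w11 / dw; out[1] = w00 / dw; out[2] = -w01 / dw;
}

struct Sym2 { double m00, m01, m11; };

static inline Sym2 inv2(double m00, double m01, double m11) {
  double det = m00 * m11 - m01 * m01;
  if (det <= 0.0) stop("2x2 matrix not positive definite");
  Sym2 r; r.m00 = m11 / det; r.m01 = -m01 / det; r.m11 = m00 / det;
  return r;
}

// draw from N(C^-1 rhs, C^-1) for 2x2 precision C; also return the mean
static inline void draw_mvn2(Rng& rng, double c00, double c01, double c11,
                             double r0, double r1,
                             double out[2], double mean[2]) {
  double l00 = std::sqrt(c00);
  double l10 = c01 / l00;
  double arg = c11 - l10 * l10;
  if (arg <= 0.0) stop("conditional precision not positive definite");
  double l11 = std::sqrt(arg);
  // solve L w = rhs, L' m = w
  double w0 = r0 / l00;
  double w1 = (r1 - l10 * w0) / l11;
  double m1 = w1 / l11;
  double m0 = (w0 - l10 * m1) / l00;
  mean[0] = m0; mean[1] = m1;
  // sample: mean + L'^-1 z
  double z0 = rng.norm(), z1 = rng.norm();
  double v1 = z1 / l11;
  double v0 = (z0 - l10 * v1) / l00;
  out[0] = m0 + v0; out[1] = m1 + v1;
}

// [[Rcpp::export(name = ".gibbs_animal")]]
List gibbs_animal(NumericVector y_mp, IntegerVector mp_obs,
                  IntegerVector afc_code, NumericVector y_afc,
                  IntegerVector animal, IntegerVector cgmp,
                  IntegerVector cgafc, NumericVector htz,
                  int n_cgmp, int n_cgafc, int n_animals,
                  IntegerVector ai_ptr, IntegerVector ai_col,
                  NumericVector ai_val,
                  double nu_g, NumericVector Vg,
                  double nu_r, NumericVector Vr,
                  NumericVector G_init, NumericVector R_init,
                  double beta_prec_mp, double beta_prec_afc,
                  int n_cycles, int burnin, int thin,
                  bool threshold, bool fix_r_afc, bool fix_variances,
                  double nu_cg, double vb_cg,
                  int warmup, int seed) {
  Rng rng(static_cast<uint64_t>(seed) * 0x9e3779b97f4a7c15ULL + 0x243f6a8885a308d3ULL);
  const int nrow = y_mp.size();
  const int q = n_animals;
  if (burnin >= n_cycles) stop("burn-in must be smaller than the chain length");
  if (thin < 1) stop("thin must be >= 1");

  // ---- row bookkeeping -----------------------------------------------------
  std::vector<char> hmp(nrow), hafc(nrow);
  for (int r = 0; r < nrow; ++r) {
    hmp[r] = mp_obs[r] != 0;
    hafc[r] = afc_code[r] >= 1;
    if (!hmp[r] && !hafc[r]) stop("row with neither trait observed");
    if (hmp[r] && cgmp[r] < 0) stop("milk row without contemporary group");
    if (hafc[r] && cgafc[r] < 0) stop("AFC row without contemporary group");
  }

  // group rows by CG level and by animal (CSR layout)
  auto build_groups = [nrow](const std::vector<int>& key, int nlev,
                             std::vector<int>& ptr, std::vector<int>& idx) {
    ptr.assign(nlev + 1, 0);
    int total = 0;
    for (int r = 0; r < nrow; ++r) if (key[r] >= 0) { ptr[key[r] + 1]++; total++; }
    for (int l = 0; l < nlev; ++l) ptr[l + 1] += ptr[l];
    idx.assign(total, 0);
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int r = 0; r < nrow; ++r)
      if (key[r] >= 0) idx[fill[key[r]]++] = r;
  };
  std::vector<int> key(nrow);
  std::vector<int> pm, im, pa, ia, pq, iq;
  for (int r = 0; r < nrow; ++r) key[r] = hmp[r] ? cgmp[r] : -1;
  build_groups(key, n_cgmp, pm, im);
  for (int r = 0; r < nrow; ++r) key[r] = hafc[r] ? cgafc[r] : -1;
  build_groups(key, n_cgafc, pa, ia);
  for (int r = 0; r < nrow; ++r) key[r] = animal[r];
  build_groups(key, q, pq, iq);

  // ---- state ---------------------------------------------------------------
  std::vector<double> bmp(n_cgmp + 1, 0.0), bafc(n_cgafc + 1, 0.0);
  std::vector<double> a0(q, 0.0), a1(q, 0.0);
  std::vector<double> emp(nrow, 0.0), eafc(nrow, 0.0);
  double G[3] = { G_init[0], G_init[3], G_init[1] };   // g00, g11, g01
  double sb2_afc = 1.0;   // threshold-trait CG-effect variance (hierarchical)
  double Rr[3] = { R_init[0], R_init[3], R_init[1] };

  // Breeding values start at 0; the warm-up phase (covariances held at
  // their starting values while locations adapt) ensures the first
  // covariance update sees a data-shaped quadratic form rather than a null
  // one, which would trap a weakly informed trait's genetic variance at 0.
  // start CG effects at their level means; slopes at 0
  for (int l = 0; l < n_cgmp; ++l) {
    double s = 0.0; int n = pm[l + 1] - pm[l];
    for (int k = pm[l]; k < pm[l + 1]; ++k) s += y_mp[im[k]];
    bmp[l] = n ? s / n : 0.0;
  }
  std::vector<double> uinit(nrow, 0.0);
  for (int r = 0; r < nrow; ++r) {
    if (afc_code[r] == 2) uinit[r] = -0.5;
    else if (afc_code[r] == 3) uinit[r] = 0.5;
    else uinit[r] = y_afc[r];
  }
  for (int l = 0; l < n_cgafc; ++l) {
    double s = 0.0; int n = pa[l + 1] - pa[l];
    for (int k = pa[l]; k < pa[l + 1]; ++k) s += uinit[ia[k]];
    bafc[l] = n ? s / n : 0.0;
  }
  for (int r = 0; r < nrow; ++r) {
    if (hmp[r]) emp[r] = y_mp[r] - bmp[cgmp[r]] - a0[animal[r]];
    if (hafc[r]) eafc[r] = uinit[r] - bafc[cgafc[r]] - a1[animal[r]];
  }

  // ---- output accumulators -------------------------------------------------
  const int n_saved = (n_cycles - burnin) / thin;
  NumericMatrix samples(n_saved, 10);
  colnames(samples) = CharacterVector::create("g_mp", "g_afc", "g_cov",
    "r_mp", "r_afc", "r_cov", "h2_mp", "h2_afc", "rg", "re");
  std::vector<double> am0(q, 0.0), am1(q, 0.0), as0(q, 0.0), as1(q, 0.0);
  std::vector<double> bm_mean(n_cgmp + 1, 0.0), ba_mean(n_cgafc + 1, 0.0);
  std::vector<double> bm_s(n_cgmp + 1, 0.0), ba_s(n_cgafc + 1, 0.0);
  std::vector<double> rb_a0(q, 0.0), rb_a1(q, 0.0);
  std::vector<double> rb_bm(n_cgmp + 1, 0.0), rb_ba(n_cgafc + 1, 0.0);
  long n_rb = 0;
  int saved = 0;

  auto fitted_afc = [&](int r) {
    return bafc[cgafc[r]] + bafc[n_cgafc] * htz[r] + a1[animal[r]];
  };

  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    if (cyc % 2048 == 0) checkUserInterrupt();
    const bool in_save = cyc > burnin;
    const bool rb_now = fix_variances && in_save;

    // residual precisions for this cycle
    Sym2 Ri = inv2(Rr[0], Rr[2], Rr[1]);
    double w_mp = 1.0 / Rr[0], w_afc = 1.0 / Rr[1];
    double cnd_sd = std::sqrt(Rr[1] - Rr[2] * Rr[2] / Rr[0]);
    double cnd_b = Rr[2] / Rr[0];

    // 1. latent liabilities (threshold model)
    if (threshold) {
      for (int r = 0; r < nrow; ++r) {
        if (afc_code[r] < 2) continue;
        double f = fitted_afc(r);
        double mu, sd;
        if (hmp[r]) { mu = f + cnd_b * emp[r]; sd = cnd_sd; }
        else { mu = f; sd = std::sqrt(Rr[1]); }
        double u = rtnorm_class(rng, mu, sd, afc_code[r] == 2 ? 1 : 2);
        eafc[r] = u - f;
      }
    }

    // 2. fixed effects, milk trait (CG levels then heterozygosity slope)
    for (int l = 0; l <= n_cgmp; ++l) {
      double C = 0.0, rhs = 0.0;
      const bool slope = l == n_cgmp;
      const int k0 = slope ? 0 : pm[l];
      const int k1 = slope ? (int)im.size() : pm[l + 1];
      const int* rows = im.data();
      for (int k = k0; k < k1; ++k) {
        int r = slope ? rows[k] : rows[k];
        double x = slope ? htz[r] : 1.0;
        double ptt = hafc[r] ? Ri.m00 : w_mp;
        double pe = hafc[r] ? (Ri.m00 * emp[r] + Ri.m01 * eafc[r])
                            : w_mp * emp[r];
        C += x * x * ptt;
        rhs += x * pe;
      }
      rhs += C * bmp[l];
      double Ct = C + beta_prec_mp;
      if (Ct <= 0.0) {
        if (slope) continue;              // covariate constant at 0: drop
        stop("empty milk fixed-effect level");
      }
      double mean = rhs / Ct;
      double bnew = mean + rng.norm() / std::sqrt(Ct);
      double del = bnew - bmp[l];
      bmp[l] = bnew;
      for (int k = k0; k < k1; ++k) {
        int r = rows[k];
        emp[r] -= (slope ? htz[r] : 1.0) * del;
      }
      if (rb_now) rb_bm[l] += mean;
    }

    // 3. fixed effects, AFC trait
    for (int l = 0; l <= n_cgafc; ++l) {
      double C = 0.0, rhs = 0.0;
      const bool slope = l == n_cgafc;
      const int k0 = slope ? 0 : pa[l];
      const int k1 = slope ? (int)ia.size() : pa[l + 1];
      const int* rows = ia.data();
      for (int k = k0; k < k1; ++k) {
        int r = rows[k];
        double x = slope ? htz[r] : 1.0;
        double ptt = hmp[r] ? Ri.m11 : w_afc;
        double pe = hmp[r] ? (Ri.m01 * emp[r] + Ri.m11 * eafc[r])
                           : w_afc * eafc[r];
        C += x * x * ptt;
        rhs += x * pe;
      }
      rhs += C * bafc[l];
      // threshold model: CG levels are a random effect with variance sb2_afc
      // (hierarchical, sampled below); the heterozygosity slope keeps the
      // fixed normal prior.  Linear model: flat priors throughout.
      double prec = slope ? beta_prec_afc
                          : (threshold ? 1.0 / sb2_afc : beta_prec_afc);
      double Ct = C + prec;
      if (Ct <= 0.0) {
        if (slope) continue;
        stop("empty AFC fixed-effect level");
      }
      double mean = rhs / Ct;
      double bnew = mean + rng.norm() / std::sqrt(Ct);
      double del = bnew - bafc[l];
      bafc[l] = bnew;
      for (int k = k0; k < k1; ++k) {
        int r = rows[k];
        eafc[r] -= (slope ? htz[r] : 1.0) * del;
      }
      if (rb_now) rb_ba[l] += mean;
    }
    // variance of the threshold-trait contemporary-group effects:
    // scaled-inverse-chi-square update (weak prior nu_b, scale V_b)
    if (threshold && n_cgafc > 0 && !fix_variances && cyc > warmup) {
      double ssb = 0.0;
      for (int l = 0; l < n_cgafc; ++l) ssb += bafc[l] * bafc[l];
      sb2_afc = (vb_cg + ssb) / rng.chisq(nu_cg + n_cgafc);
    }

    // 4. breeding values, one bivariate block per animal
    Sym2 Gi = inv2(G[0], G[2], G[1]);
    for (int i = 0; i < q; ++i) {
      double c00 = 0.0, c01 = 0.0, c11 = 0.0, r0 = 0.0, r1 = 0.0;
      for (int k = pq[i]; k < pq[i + 1]; ++k) {
        int r = iq[k];
        if (hmp[r] && hafc[r]) {
          c00 += Ri.m00; c01 += Ri.m01; c11 += Ri.m11;
          r0 += Ri.m00 * emp[r] + Ri.m01 * eafc[r];
          r1 += Ri.m01 * emp[r] + Ri.m11 * eafc[r];
        } else if (hmp[r]) {
          c00 += w_mp; r0 += w_mp * emp[r];
        } else {
          c11 += w_afc; r1 += w_afc * eafc[r];
        }
      }
      r0 += c00 * a0[i] + c01 * a1[i];
      r1 += c01 * a0[i] + c11 * a1[i];
      // genetic contribution through A^-1
      double dii = 0.0, s0 = 0.0, s1 = 0.0;
      for (int k = ai_ptr[i]; k < ai_ptr[i + 1]; ++k) {
        int j = ai_col[k];
        double v = ai_val[k];
        if (j == i) { dii = v; continue; }
        s0 += v * a0[j];
        s1 += v * a1[j];
      }
      c00 += dii * Gi.m00; c01 += dii * Gi.m01; c11 += dii * Gi.m11;
      r0 -= Gi.m00 * s0 + Gi.m01 * s1;
      r1 -= Gi.m01 * s0 + Gi.m11 * s1;
      double anew[2], amean[2];
      draw_mvn2(rng, c00, c01, c11, r0, r1, anew, amean);
      double d0 = anew[0] - a0[i], d1 = anew[1] - a1[i];
      a0[i] = anew[0]; a1[i] = anew[1];
      for (int k = pq[i]; k < pq[i + 1]; ++k) {
        int r = iq[k];
        if (hmp[r]) emp[r] -= d0;
        if (hafc[r]) eafc[r] -= d1;
      }
      if (rb_now) { rb_a0[i] += amean[0]; rb_a1[i] += amean[1]; }
    }
    if (rb_now) n_rb++;

    // warm-up: hold (co)variances at their starting values while the
    // location effects equilibrate to the data, so the first covariance
    // updates see a quadratic form that reflects the data rather than the
    // arbitrary start (guards the weakly informed threshold trait against
    // starting in a degenerate regime)
    if (!fix_variances && cyc > warmup) {
      // 5. additive covariance: IW(nu_g + q, Vg + a' A^-1 a)
      double S[3] = { Vg[0], Vg[3], Vg[1] };
      for (int i = 0; i < q; ++i) {
        for (int k = ai_ptr[i]; k < ai_ptr[i + 1]; ++k) {
          int j = ai_col[k]; double v = ai_val[k];
          S[0] += v * a0[i] * a0[j];
          S[1] += v * a1[i] * a1[j];
          S[2] += v * a0[i] * a1[j];
        }
      }
      riwish2(rng, nu_g + q, S, G);

      // 6. residual covariance: augment missing-trait residuals, IW update
      double Se[3] = { Vr[0], Vr[3], Vr[1] };
      double cb_mp = Rr[2] / Rr[1], cs_mp = std::sqrt(Rr[0] - Rr[2] * Rr[2] / Rr[1]);
      for (int r = 0; r < nrow; ++r) {
        double e0 = emp[r], e1 = eafc[r];
        if (!hmp[r]) e0 = cb_mp * e1 + cs_mp * rng.norm();
        else if (!hafc[r]) e1 = cnd_b * e0 + cnd_sd * rng.norm();
        Se[0] += e0 * e0; Se[1] += e1 * e1; Se[2] += e0 * e1;
      }
      if (threshold && fix_r_afc) {
        // identification: the liability residual variance stays fixed at 1.
        // Draw the remaining residual parameters from their exact
        // conditional under the inverse-Wishart: with the partition
        // (MP | AFC), r_mp.afc ~ IW1(nu, S_mp.afc) and the regression
        // b = r_cov/r_afc ~ N(S12/S22, r_mp.afc/S22), independent of r_afc.
        double s112 = Se[0] - Se[2] * Se[2] / Se[1];
        double r112 = s112 / rng.chisq(nu_r + nrow);
        double b = Se[2] / Se[1] + rng.norm() * std::sqrt(r112 / Se[1]);
        Rr[1] = 1.0;
        Rr[2] = b;
        Rr[0] = r112 + b * b;
      } else {
        riwish2(rng, nu_r + nrow, Se, Rr);
      }
      // joint Metropolis scale move on the AFC (liability) dimension:
      // propose (u, beta_afc, a_afc, g_afc, g_cov) -> (lam*u, lam*beta,
      // lam*a, lam^2*g_afc, lam*g_cov) with the residual structure held
      // fixed.  The breeding-value Jacobian cancels against the genetic
      // prior normalization, so the acceptance ratio involves only the
      // liability residuals, the fixed-effect prior, the inverse-Wishart
      // prior on G and the remaining Jacobian terms.  Single-site updates
      // inflate or deflate this scale only one coordinate at a time and mix
      // across scale regimes impractically slowly; this move restores that
      // mixing and lets the within-cell class mixture anchor the scale.
      if (threshold && fix_r_afc) {
        Sym2 Ri2 = inv2(Rr[0], Rr[2], Rr[1]);
        double w2 = 1.0 / Rr[1];
        double lam = std::exp(0.1 * rng.norm());
        double se11 = 0.0, se01 = 0.0;
        int n_afc = 0;
        for (int r = 0; r < nrow; ++r) {
          if (!hafc[r]) continue;
          n_afc++;
          if (hmp[r]) {
            se11 += Ri2.m11 * eafc[r] * eafc[r];
            se01 += Ri2.m01 * emp[r] * eafc[r];
          } else {
            se11 += w2 * eafc[r] * eafc[r];
          }
        }
        // CG levels scale with their hierarchical variance (sb2 -> lam^2 sb2),
        // so their Jacobian cancels against the prior normalization and only
        // the sb2 hyperprior contributes; the heterozygosity slope keeps its
        // fixed normal prior.
        double slope2 = bafc[n_cgafc] * bafc[n_cgafc];
        double logp = -0.5 * ((lam * lam - 1.0) * se11 + 2.0 * (lam - 1.0) * se01)
          + n_afc * std::log(lam)
          + std::log(lam)
          - 0.5 * (lam * lam - 1.0) * slope2 * beta_prec_afc
          + (2.0 - (nu_cg + 2.0)) * std::log(lam)
          - 0.5 * vb_cg * (1.0 / (lam * lam * sb2_afc) - 1.0 / sb2_afc)
          + 3.0 * std::log(lam);
        // inverse-Wishart prior on G at the proposed vs current value
        auto log_iw2 = [&](double g00, double g11, double g01) {
          double det = g00 * g11 - g01 * g01;
          if (det <= 0.0 || g00 <= 0.0) return -1e300;
          Sym2 gi = inv2(g00, g01, g11);
          return -0.5 * (nu_g + 3.0) * std::log(det)
            - 0.5 * (Vg[0] * gi.m00 + Vg[3] * gi.m11 + 2.0 * Vg[1] * gi.m01);
        };
        logp += log_iw2(G[0], lam * lam * G[1], lam * G[2])
              - log_iw2(G[0], G[1], G[2]);
        if (std::log(rng.unif()) < logp) {
          for (int i = 0; i < q; ++i) a1[i] *= lam;
          for (int l = 0; l <= n_cgafc; ++l) bafc[l] *= lam;
          for (int r = 0; r < nrow; ++r) if (hafc[r]) eafc[r] *= lam;
          G[1] *= lam * lam; G[2] *= lam;
          sb2_afc *= lam * lam;
        }
      }
      // linear-model counterpart for the weakly informed AFC trait: rescale
      // (a_afc, g_afc, g_cov) jointly with the data held fixed.  Escapes the
      // near-zero absorbing regime of the genetic variance, which single-site
      // updates leave only at a geometric-random-walk pace.
      if (!threshold) {
        Sym2 Ri2 = inv2(Rr[0], Rr[2], Rr[1]);
        double w2 = 1.0 / Rr[1];
        double lam = std::exp(0.1 * rng.norm());
        // residual change: e1 -> e1 - (lam - 1) * a1[animal]
        double d11 = 0.0, d01 = 0.0, dcross = 0.0;
        for (int r = 0; r < nrow; ++r) {
          if (!hafc[r]) continue;
          double av = a1[animal[r]];
          double p11 = hmp[r] ? Ri2.m11 : w2;
          double p01 = hmp[r] ? Ri2.m01 : 0.0;
          // e1'^2 - e1^2 = (lam-1)^2 av^2 - 2 (lam-1) av e1
          d11 += p11 * av * av;
          dcross += p11 * av * eafc[r];
          d01 += p01 * emp[r] * av;
        }
        double dl = lam - 1.0;
        double logp = -0.5 * (dl * dl * d11 - 2.0 * dl * dcross)
          - (-dl) * d01   // cross term: 2 * P01 * e0 * (e1'-e1) / -2
          + 3.0 * std::log(lam);
        auto log_iw2 = [&](double g00, double g11, double g01) {
          double det = g00 * g11 - g01 * g01;
          if (det <= 0.0 || g00 <= 0.0) return -1e300;
          Sym2 gi = inv2(g00, g01, g11);
          return -0.5 * (nu_g + 3.0) * std::log(det)
            - 0.5 * (Vg[0] * gi.m00 + Vg[3] * gi.m11 + 2.0 * Vg[1] * gi.m01);
        };
        logp += log_iw2(G[0], lam * lam * G[1], lam * G[2])
              - log_iw2(G[0], G[1], G[2]);
        if (std::log(rng.unif()) < logp) {
          for (int r = 0; r < nrow; ++r)
            if (hafc[r]) eafc[r] -= dl * a1[animal[r]];
          for (int i = 0; i < q; ++i) a1[i] *= lam;
          G[1] *= lam * lam; G[2] *= lam;
        }
      }
      if (!R_finite(G[0]) || !R_finite(Rr[0]))
        stop("non-finite covariance state at cycle %d", cyc);
    }

    // 7. save
    if (in_save && (cyc - burnin) % thin == 0) {
      samples(saved, 0) = G[0]; samples(saved, 1) = G[1];
      samples(saved, 2) = G[2];
      samples(saved, 3) = Rr[0]; samples(saved, 4) = Rr[1];
      samples(saved, 5) = Rr[2];
      samples(saved, 6) = G[0] / (G[0] + Rr[0]);
      samples(saved, 7) = G[1] / (G[1] + Rr[1]);
      samples(saved, 8) = G[2] / std::sqrt(G[0] * G[1]);
      samples(saved, 9) = Rr[2] / std::sqrt(Rr[0] * Rr[1]);
      saved++;
      // Welford accumulation of location-effect posteriors
      for (int i = 0; i < q; ++i) {
        double d = a0[i] - am0[i]; am0[i] += d / saved;
        as0[i] += d * (a0[i] - am0[i]);
        d = a1[i] - am1[i]; am1[i] += d / saved;
        as1[i] += d * (a1[i] - am1[i]);
      }
      for (int l = 0; l <= n_cgmp; ++l) {
        double d = bmp[l] - bm_mean[l]; bm_mean[l] += d / saved;
        bm_s[l] += d * (bmp[l] - bm_mean[l]);
      }
      for (int l = 0; l <= n_cgafc; ++l) {
        double d = bafc[l] - ba_mean[l]; ba_mean[l] += d / saved;
        ba_s[l] += d * (bafc[l] - ba_mean[l]);
      }
    }
  }

  auto sd_of = [](std::vector<double>& s, int n) {
    NumericVector out(s.size());
    for (size_t k = 0; k < s.size(); ++k)
      out[k] = n > 1 ? std::sqrt(s[k] / (n - 1)) : 0.0;
    return out;
  };
  auto scale_by = [](std::vector<double>& v, double c) {
    NumericVector out(v.size());
    for (size_t k = 0; k < v.size(); ++k) out[k] = v[k] * c;
    return out;
  };
  double rbn = n_rb > 0 ? 1.0 / n_rb : 0.0;
  return List::create(
    _["samples"] = samples,
    _["a_mean"] = cbind(NumericVector(am0.begin(), am0.end()),
                        NumericVector(am1.begin(), am1.end())),
    _["a_sd"] = cbind(sd_of(as0, saved), sd_of(as1, saved)),
    _["beta_mp_mean"] = NumericVector(bm_mean.begin(), bm_mean.end()),
    _["beta_mp_sd"] = sd_of(bm_s, saved),
    _["beta_afc_mean"] = NumericVector(ba_mean.begin(), ba_mean.end()),
    _["beta_afc_sd"] = sd_of(ba_s, saved),
    _["a_rb"] = cbind(scale_by(rb_a0, rbn), scale_by(rb_a1, rbn)),
    _["beta_mp_rb"] = scale_by(rb_bm, rbn),
    _["beta_afc_rb"] = scale_by(rb_ba, rbn),
    _["n_saved"] = saved);
}

// helper RNG for the exported primitives: seeded from R's stream so that
// set.seed() still controls them
static Rng r_seeded_rng() {
  return Rng(static_cast<uint64_t>(unif_rand() * 9007199254740992.0));
}

// [[Rcpp::export(name = ".riwish2")]]
NumericMatrix riwish2_r(double df, NumericMatrix S) {
  Rng rng = r_seeded_rng();
  if (S.nrow() == 1) {
    // univariate: G = S / chisq(df)
    NumericMatrix out(1, 1);
    out(0, 0) = S(0, 0) / rng.chisq(df);
    return out;
  }
  double Sv[3] = { S(0, 0), S(1, 1), S(0, 1) };
  double G[3];
  riwish2(rng, df, Sv, G);
  NumericMatrix out(2, 2);
  out(0, 0) = G[0]; out(1, 1) = G[1]; out(0, 1) = out(1, 0) = G[2];
  return out;
}

// [[Rcpp::export(name = ".rtruncnorm_class")]]
NumericVector rtruncnorm_class(int n, double mean, double sd, int cls) {
  if (cls != 1 && cls != 2) stop("class must be 1 or 2");
  Rng rng = r_seeded_rng();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm_class(rng, mean, sd, cls);
  return out;
}
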