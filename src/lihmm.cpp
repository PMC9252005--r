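#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Diploid Li-Stephens haplotype-copying HMM over one chromosome.
//
// Hidden state: an ordered pair (i, j) of reference haplotypes, one per
// chromosome copy. Between adjacent sites each copy independently
// switches with probability theta = 1 - exp(-4 * Ne * dM / K) to a
// uniformly chosen haplotype (including itself), so the K^2-state
// transition factorises into two rank-one K-state operators and a full
// update costs O(K^2). Emission at a typed site with genotype g treats
// g as an unordered allele-count observation against the copied alleles
// d = h_i + h_j: P(g | d) = (1-eps)^(2-|g-d|) * eps^|g-d|. Untyped or
// missing sites emit 1.
//
// The forward pass stores the (normalised, symmetric) forward matrix at
// typed sites only. Posteriors at untyped sites are recovered exactly
// during the backward pass: the flanking messages propagated through
// the factorised transition expand into rank-one corrections of the
// stored matrices, so after an O(K^2) precomputation per interval each
// untyped site costs O(K * km) where km is the number of reference
// haplotypes carrying the alt allele there.

static inline double theta_of(double dM, double ne, int K, double min_switch) {
  double th = 1.0 - std::exp(-4.0 * ne * dM / K);
  return th < min_switch ? min_switch : th;
}

// In-place factorised transition A <- T_theta A T_theta (both axes);
// preserves symmetry.
static void transition(std::vector<double>& A, int K, double theta) {
  double c = 1.0 - theta, d = theta / K;
  std::vector<double> R(K, 0.0);
  double S = 0.0;
  for (int i = 0; i < K; ++i) {
    const double* Ai = &A[(size_t)i * K];
    double s = 0.0;
    for (int j = 0; j < K; ++j) s += Ai[j];
    R[i] = s; S += s;
  }
  double c2 = c * c, cd = c * d, d2 = d * d * S;
  for (int i = 0; i < K; ++i) {
    double* Ai = &A[(size_t)i * K];
    double ri = cd * R[i];
    for (int j = 0; j < K; ++j)
      Ai[j] = c2 * Ai[j] + ri + cd * R[j] + d2;
  }
}

static void normalise(std::vector<double>& A) {
  double s = 0.0;
  for (double a : A) s += a;
  if (s <= 0.0) stop("forward-backward underflow: zero mass");
  for (double& a : A) a /= s;
}

// Exact posterior moments of the copied dose at one site from the full
// K x K state weight matrix G (used at typed sites, where G is cheap).
static void moments_full(const std::vector<double>& G, const int* hm, int K,
                         double& dmean, double& dvar) {
  double Z = 0.0, s1 = 0.0, s2 = 0.0;
  for (int i = 0; i < K; ++i) {
    const double* Gi = &G[(size_t)i * K];
    for (int j = 0; j < K; ++j) {
      double w = Gi[j];
      int dd = hm[i] + hm[j];
      Z += w; s1 += w * dd; s2 += w * dd * dd;
    }
  }
  dmean = s1 / Z;
  double v = s2 / Z - dmean * dmean;
  dvar = v > 0.0 ? v : 0.0;
}

// Per-interval workspace for the factorised posterior at untyped sites.
// A is the forward matrix at the left typed flank, B the backward
// message (emission times beta) at the right flank; both symmetric.
// For an untyped site the posterior state weight is
//   W_ij = [a A_ij + b (Ra_i + Ra_j) + e] * [f B_ij + g (Rb_i + Rb_j) + k]
// with a = c1^2, b = c1 d1, e = d1^2 Sa (and f, g, k likewise from the
// right-hand switch probability), and the dose moments need only
//   Z = sum W, s1 = sum W (h_i + h_j) = 2 sum_i h_i rowsum(W)_i,
//   s2 = s1 + 2 h' W h,
// all of which reduce to the precomputed scalars/vectors below plus
// three sparse gathers qa = A h, qb = B h, qab = (A o B) h.
struct IntervalWs {
  int K;
  double Sa, Sb, S_AB, P_ab;
  std::vector<double> Ra, Rb, Tab, Ua, Ub;
  std::vector<double> qa, qb, qab;

  void prepare(const std::vector<double>& A, const std::vector<double>& B,
               int K_) {
    K = K_;
    Ra.assign(K, 0.0); Rb.assign(K, 0.0); Tab.assign(K, 0.0);
    Ua.assign(K, 0.0); Ub.assign(K, 0.0);
    qa.resize(K); qb.resize(K); qab.resize(K);
    Sa = Sb = S_AB = P_ab = 0.0;
    for (int i = 0; i < K; ++i) {
      const double* Ai = &A[(size_t)i * K];
      const double* Bi = &B[(size_t)i * K];
      double ra = 0.0, rb = 0.0, tab = 0.0;
      for (int j = 0; j < K; ++j) {
        ra += Ai[j]; rb += Bi[j]; tab += Ai[j] * Bi[j];
      }
      Ra[i] = ra; Rb[i] = rb; Tab[i] = tab;
      Sa += ra; Sb += rb; S_AB += tab;
    }
    for (int i = 0; i < K; ++i) {
      const double* Ai = &A[(size_t)i * K];
      const double* Bi = &B[(size_t)i * K];
      double ua = 0.0, ub = 0.0;
      for (int j = 0; j < K; ++j) {
        ua += Ai[j] * Rb[j];
        ub += Bi[j] * Ra[j];
      }
      Ua[i] = ua; Ub[i] = ub;
      P_ab += Ra[i] * Rb[i];
    }
  }

  void site(const std::vector<double>& A, const std::vector<double>& B,
            const std::vector<int>& ones, double th1, double th2,
            double& dmean, double& dvar) {
    const int km = (int)ones.size();
    double c1 = 1.0 - th1, d1 = th1 / K, c2 = 1.0 - th2, d2 = th2 / K;
    double a = c1 * c1, b = c1 * d1, e = d1 * d1 * Sa;
    double f = c2 * c2, g = c2 * d2, k = d2 * d2 * Sb;

    // sparse gathers over the alt-carrying haplotypes (symmetric A, B:
    // column j equals row j, so reads are contiguous)
    std::fill(qa.begin(), qa.end(), 0.0);
    std::fill(qb.begin(), qb.end(), 0.0);
    std::fill(qab.begin(), qab.end(), 0.0);
    for (int j : ones) {
      const double* Aj = &A[(size_t)j * K];
      const double* Bj = &B[(size_t)j * K];
      for (int i = 0; i < K; ++i) {
        qa[i] += Aj[i];
        qb[i] += Bj[i];
        qab[i] += Aj[i] * Bj[i];
      }
    }
    double sh_Ra = 0, sh_Rb = 0, sh_Tab = 0, sh_Ua = 0, sh_Ub = 0,
      sh_RaRb = 0, sh_qa = 0, sh_qb = 0, sh_qab = 0, sh_Rbqa = 0,
      sh_Raqb = 0;
    for (int i : ones) {
      sh_Ra += Ra[i]; sh_Rb += Rb[i]; sh_Tab += Tab[i];
      sh_Ua += Ua[i]; sh_Ub += Ub[i]; sh_RaRb += Ra[i] * Rb[i];
      sh_qa += qa[i]; sh_qb += qb[i]; sh_qab += qab[i];
      sh_Rbqa += Rb[i] * qa[i]; sh_Raqb += Ra[i] * qb[i];
    }

    double Z = a * f * S_AB + (a * g + b * f) * 2.0 * P_ab + a * k * Sa +
      b * g * (2.0 * K * P_ab + 2.0 * Sa * Sb) + b * k * 2.0 * K * Sa +
      e * f * Sb + e * g * 2.0 * K * Sb + e * k * (double)K * K;

    double half_s1 =
      a * f * sh_Tab +
      a * g * (sh_RaRb + sh_Ua) +
      a * k * sh_Ra +
      b * f * (sh_RaRb + sh_Ub) +
      b * g * (K * sh_RaRb + Sb * sh_Ra + Sa * sh_Rb + km * P_ab) +
      b * k * (K * sh_Ra + km * Sa) +
      e * f * sh_Rb +
      e * g * (K * sh_Rb + km * Sb) +
      e * k * (double)K * km;
    double s1 = 2.0 * half_s1;

    double hWh =
      a * f * sh_qab +
      a * g * 2.0 * sh_Rbqa +
      a * k * sh_qa +
      b * f * 2.0 * sh_Raqb +
      b * g * (2.0 * km * sh_RaRb + 2.0 * sh_Ra * sh_Rb) +
      b * k * 2.0 * km * sh_Ra +
      e * f * sh_qb +
      e * g * 2.0 * km * sh_Rb +
      e * k * (double)km * km;
    double s2 = s1 + 2.0 * hWh;

    dmean = s1 / Z;
    double v = s2 / Z - dmean * dmean;
    dvar = v > 0.0 ? v : 0.0;
  }
};

// [[Rcpp::export(name = ".ls_impute_chrom")]]
List ls_impute_chrom(IntegerVector gt, IntegerMatrix H, NumericVector map,
                     double ne, double err, double min_switch) {
  const int K = H.nrow();
  const int M = H.ncol();
  if (gt.size() != M || map.size() != M)
    stop("gt, map and reference columns must align");

  NumericVector ds(M), pvar(M);

  std::vector<int> ts;
  ts.reserve(M);
  for (int m = 0; m < M; ++m)
    if (gt[m] != NA_INTEGER) ts.push_back(m);
  const int T = (int)ts.size();

  // alt-carrier index lists per site, plus dense columns for typed sites
  std::vector<std::vector<int>> ones(M);
  std::vector<int> h((size_t)K * M);
  for (int m = 0; m < M; ++m) {
    int* hm = &h[(size_t)m * K];
    for (int i = 0; i < K; ++i) {
      hm[i] = H(i, m);
      if (hm[i]) ones[m].push_back(i);
    }
  }

  double etab[3][3];
  for (int g = 0; g < 3; ++g)
    for (int d = 0; d < 3; ++d) {
      int mism = std::abs(g - d);
      etab[g][d] = std::pow(err, mism) * std::pow(1.0 - err, 2 - mism);
    }

  const std::vector<double> uniform((size_t)K * K, 1.0 / ((double)K * K));

  if (T == 0) {
    for (int m = 0; m < M; ++m) {
      double dm, dv;
      moments_full(uniform, &h[(size_t)m * K], K, dm, dv);
      ds[m] = dm; pvar[m] = dv;
    }
    return List::create(_["ds"] = ds, _["post_var"] = pvar);
  }

  // ---- forward pass over typed sites ----
  std::vector<std::vector<double>> alpha(T);
  {
    std::vector<double> A = uniform;
    for (int t = 0; t < T; ++t) {
      if (t > 0)
        transition(A, K, theta_of(map[ts[t]] - map[ts[t - 1]], ne, K, min_switch));
      const int* hm = &h[(size_t)ts[t] * K];
      const double* eg = etab[gt[ts[t]]];
      for (int i = 0; i < K; ++i) {
        double* Ai = &A[(size_t)i * K];
        for (int j = 0; j < K; ++j)
          Ai[j] *= eg[hm[i] + hm[j]];
      }
      normalise(A);
      alpha[t] = A;
    }
  }

  // ---- backward pass, emitting posteriors on the fly ----
  std::vector<double> beta((size_t)K * K, 1.0), bmsg((size_t)K * K),
    G((size_t)K * K);
  IntervalWs ws;

  // typed site ts[T-1] and the sites after it (backward message is flat,
  // handled as B = all-ones with no right-hand transition)
  {
    const std::vector<double>& A = alpha[T - 1];
    double dm, dv;
    moments_full(A, &h[(size_t)ts[T - 1] * K], K, dm, dv);
    ds[ts[T - 1]] = dm; pvar[ts[T - 1]] = dv;
    if (ts[T - 1] < M - 1) {
      std::vector<double> Bflat((size_t)K * K, 1.0);
      ws.prepare(A, Bflat, K);
      for (int m = ts[T - 1] + 1; m < M; ++m) {
        double th1 = theta_of(map[m] - map[ts[T - 1]], ne, K, min_switch);
        ws.site(A, Bflat, ones[m], th1, 0.0, dm, dv);
        ds[m] = dm; pvar[m] = dv;
      }
    }
  }

  for (int t = T - 2; t >= 0; --t) {
    // fold emission at typed site ts[t+1] into the backward message
    const int* hm = &h[(size_t)ts[t + 1] * K];
    const double* eg = etab[gt[ts[t + 1]]];
    for (int i = 0; i < K; ++i) {
      const double* bi = &beta[(size_t)i * K];
      double* mi = &bmsg[(size_t)i * K];
      for (int j = 0; j < K; ++j)
        mi[j] = bi[j] * eg[hm[i] + hm[j]];
    }

    const std::vector<double>& A = alpha[t];

    if (ts[t + 1] - ts[t] > 1) {
      ws.prepare(A, bmsg, K);
      for (int m = ts[t] + 1; m < ts[t + 1]; ++m) {
        double th1 = theta_of(map[m] - map[ts[t]], ne, K, min_switch);
        double th2 = theta_of(map[ts[t + 1]] - map[m], ne, K, min_switch);
        double dm, dv;
        ws.site(A, bmsg, ones[m], th1, th2, dm, dv);
        ds[m] = dm; pvar[m] = dv;
      }
    }

    // posterior at typed site ts[t]
    beta = bmsg;
    transition(beta, K, theta_of(map[ts[t + 1]] - map[ts[t]], ne, K, min_switch));
    normalise(beta);
    for (size_t i = 0; i < (size_t)K * K; ++i) G[i] = A[i] * beta[i];
    double dm, dv;
    moments_full(G, &h[(size_t)ts[t] * K], K, dm, dv);
    ds[ts[t]] = dm; pvar[ts[t]] = dv;
  }

  // sites before the first typed site: uniform prior on the left
  if (ts[0] > 0) {
    const int* hm = &h[(size_t)ts[0] * K];
    const double* eg = etab[gt[ts[0]]];
    for (int i = 0; i < K; ++i) {
      const double* bi = &beta[(size_t)i * K];
      double* mi = &bmsg[(size_t)i * K];
      for (int j = 0; j < K; ++j)
        mi[j] = bi[j] * eg[hm[i] + hm[j]];
    }
    ws.prepare(uniform, bmsg, K);
    for (int m = 0; m < ts[0]; ++m) {
      double th2 = theta_of(map[ts[0]] - map[m], ne, K, min_switch);
      double dm, dv;
      ws.site(uniform, bmsg, ones[m], 0.0, th2, dm, dv);
      ds[m] = dm; pvar[m] = dv;
    }
  }

  return List::create(_["ds"] = ds, _["post_var"] = pvar);
}
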