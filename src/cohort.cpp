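#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simulate one GWAS cohort under the structural model
//   X = sum_j beta_x[j] G_j + U + eps_X
//   Y = sum_j alpha[j] G_j + theta * X + U + eps_Y
// with G_j ~ Binomial(2, maf[j]) and U, eps_X, eps_Y independent normals,
// and reduce it to per-SNP simple-regression slopes and SEs for the
// requested trait (exposure X or outcome Y).
//
// Genotypes are held as raw bytes so an n = 100,000 x m = 100 cohort stays
// around 10 MB; the Binomial(2, p) draw is the sum of two uniform
// comparisons, which keeps the cost of the 2*n*m RNG calls low. Uses R's
// RNG stream, so results are reproducible under set.seed().

// [[Rcpp::export]]
List cohort_gwas_cpp(const int n, const NumericVector beta_x,
                     const NumericVector alpha, const double theta,
                     const NumericVector maf, const double confounder_sd,
                     const double eps_x_sd, const double eps_y_sd,
                     const bool outcome) {
  const int m = beta_x.size();
  std::vector<unsigned char> G((size_t)n * (size_t)m);
  std::vector<double> gb(n, 0.0);  // G %*% beta_x
  std::vector<double> ga;          // G %*% alpha (outcome cohorts only)
  if (outcome) ga.assign(n, 0.0);

  for (int j = 0; j < m; ++j) {
    const double p = maf[j], bj = beta_x[j];
    const double aj = outcome ? alpha[j] : 0.0;
    unsigned char *col = &G[(size_t)j * (size_t)n];
    for (int i = 0; i < n; ++i) {
      const unsigned char g =
          (unif_rand() < p ? 1 : 0) + (unif_rand() < p ? 1 : 0);
      col[i] = g;
      if (g) {
        gb[i] += bj * g;
        if (outcome) ga[i] += aj * g;
      }
    }
  }

  std::vector<double> t(n);
  if (!outcome) {
    for (int i = 0; i < n; ++i)
      t[i] = gb[i] + confounder_sd * norm_rand() + eps_x_sd * norm_rand();
  } else {
    // the same confounder draw U enters both X and Y
    for (int i = 0; i < n; ++i) {
      const double u = confounder_sd * norm_rand();
      const double x = gb[i] + u + eps_x_sd * norm_rand();
      t[i] = ga[i] + theta * x + u + eps_y_sd * norm_rand();
    }
  }

  double tsum = 0.0;
  for (int i = 0; i < n; ++i) tsum += t[i];
  const double tbar = tsum / n;
  double tss = 0.0;
  for (int i = 0; i < n; ++i) tss += (t[i] - tbar) * (t[i] - tbar);

  NumericVector beta(m), se(m);
  for (int j = 0; j < m; ++j) {
    const unsigned char *col = &G[(size_t)j * (size_t)n];
    double sg = 0.0, sgg = 0.0, sgt = 0.0;
    for (int i = 0; i < n; ++i) {
      const double g = col[i];
      sg += g;
      sgg += g * g;
      sgt += g * t[i];
    }
    const double sxx = sgg - sg * sg / n;
    if (sxx <= 0.0)
      stop("monomorphic SNP (zero genotype variance) at index %d", j + 1);
    const double b = (sgt - sg * tbar) / sxx;
    double rss = tss - b * b * sxx;
    if (rss < 0.0) rss = 0.0;
    beta[j] = b;
    se[j] = std::sqrt(rss / ((double)(n - 2) * sxx));
  }
  return List::create(_["beta"] = beta, _["se"] = se);
}
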