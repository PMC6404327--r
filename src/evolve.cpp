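#include <Rcpp.h>
using namespace Rcpp;

// Inner loop of the evolutionary algorithm over a population of 64x21
// row-stochastic code matrices. Uses R's RNG throughout, so a run is fully
// reproducible from set.seed() on the R side.
//
// Per generation:
//   1. mutation: for each individual, `rows_per_ind` codon rows receive
//      additive N(0, sigma) noise, are clipped to `floor_p` and renormalised;
//   2. stochastic fitness: one representative codon is drawn per label by
//      Bayes' rule (column mass), and F is the product over labels of the
//      neighbourhood sums of P(l | c') -- the factorised form of the
//      forward recursion;
//   3. fitness-proportional resampling with replacement (roulette wheel).
//
// Trajectory rows (mean entropy, best/mean fitness) are recorded at
// generation 0, every `log_every` generations, and at the final generation.

static const int NC = 64;
static const int NL = 21;

static double matrix_entropy(const double *p) {
  double h = 0.0;
  for (int i = 0; i < NC * NL; ++i) {
    if (p[i] > 0.0) h -= p[i] * std::log(p[i]);
  }
  return h;
}

// [[Rcpp::export]]
List cpp_evolve(NumericVector pop0, int generations, IntegerMatrix nbhd,
                double sigma, int rows_per_ind, double floor_p,
                int log_every, double mutation_prob, bool single_entry) {
  IntegerVector dims = pop0.attr("dim");
  if (dims.size() != 3 || dims[0] != NC || dims[1] != NL)
    stop("population must be a 64 x 21 x n array");
  const int n = dims[2];
  const int nbsize = nbhd.nrow();
  if (nbhd.ncol() != NC) stop("neighbourhood table must have 64 columns");
  if (generations < 0) stop("generations must be >= 0");
  if (log_every < 1) log_every = 1;

  // 0-based neighbourhood table
  std::vector<int> nb(nbsize * NC);
  for (int c = 0; c < NC; ++c)
    for (int j = 0; j < nbsize; ++j) nb[c * nbsize + j] = nbhd(j, c) - 1;

  const int msize = NC * NL;
  std::vector<double> pop(pop0.begin(), pop0.end());
  std::vector<double> buf(pop.size());
  std::vector<double> fit(n), colsum(NL), cum(n);

  std::vector<double> tr_gen, tr_h, tr_best, tr_mean;
  int zero_fitness_events = 0;

  RNGScope scope;

  // stochastic fitness of individual i (fresh label draw)
  auto eval_fitness = [&](const double *p) {
    for (int l = 0; l < NL; ++l) {
      double s = 0.0;
      for (int c = 0; c < NC; ++c) s += p[l * NC + c];
      colsum[l] = s;
    }
    double F = 1.0;
    for (int l = 0; l < NL; ++l) {
      if (colsum[l] <= 0.0) return 0.0;  // degenerate label column
      double u = unif_rand() * colsum[l];
      int cl = NC - 1;
      double acc = 0.0;
      for (int c = 0; c < NC; ++c) {
        acc += p[l * NC + c];
        if (acc >= u) { cl = c; break; }
      }
      const int *Ncl = &nb[cl * nbsize];
      double s = 0.0;
      for (int j = 0; j < nbsize; ++j) s += p[l * NC + Ncl[j]];
      F *= s;
    }
    return F;
  };

  auto log_row = [&](int gen) {
    double h = 0.0, fb = 0.0, fm = 0.0;
    for (int i = 0; i < n; ++i) {
      h += matrix_entropy(&pop[(size_t)i * msize]);
      fm += fit[i];
      if (fit[i] > fb) fb = fit[i];
    }
    tr_gen.push_back(gen);
    tr_h.push_back(h / n);
    tr_best.push_back(fb);
    tr_mean.push_back(fm / n);
  };

  // generation 0: evaluate the initial population (no mutation/selection)
  for (int i = 0; i < n; ++i) fit[i] = eval_fitness(&pop[(size_t)i * msize]);
  log_row(0);

  for (int gen = 1; gen <= generations; ++gen) {
    // mutation
    if (sigma > 0.0 && rows_per_ind > 0 && mutation_prob > 0.0) {
      for (int i = 0; i < n; ++i) {
        if (mutation_prob < 1.0 && unif_rand() >= mutation_prob) continue;
        double *p = &pop[(size_t)i * msize];
        for (int rmut = 0; rmut < rows_per_ind; ++rmut) {
          int r = (int)(unif_rand() * NC);
          if (r == NC) r = NC - 1;
          if (single_entry) {
            int l0 = (int)(unif_rand() * NL);
            if (l0 == NL) l0 = NL - 1;
            double v = p[l0 * NC + r] + norm_rand() * sigma;
            if (v < floor_p) v = floor_p;
            p[l0 * NC + r] = v;
          } else {
            for (int l = 0; l < NL; ++l) {
              double v = p[l * NC + r] + norm_rand() * sigma;
              if (v < floor_p) v = floor_p;
              p[l * NC + r] = v;
            }
          }
          double s = 0.0;
          for (int l = 0; l < NL; ++l) s += p[l * NC + r];
          for (int l = 0; l < NL; ++l) p[l * NC + r] /= s;
        }
      }
    }
    // fitness
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      fit[i] = eval_fitness(&pop[(size_t)i * msize]);
      tot += fit[i];
      cum[i] = tot;
    }
    if (gen % log_every == 0 || gen == generations) log_row(gen);
    // selection (roulette wheel; uniform fallback if all fitnesses are 0)
    for (int i = 0; i < n; ++i) {
      int j;
      if (tot > 0.0) {
        double u = unif_rand() * tot;
        j = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (j >= n) j = n - 1;
      } else {
        j = (int)(unif_rand() * n);
        if (j == n) j = n - 1;
      }
      std::copy(&pop[(size_t)j * msize], &pop[(size_t)j * msize] + msize,
                &buf[(size_t)i * msize]);
    }
    if (tot <= 0.0) ++zero_fitness_events;
    std::swap(pop, buf);
  }

  NumericVector final_pop(pop.begin(), pop.end());
  final_pop.attr("dim") = dims;
  return List::create(
    _["generation"] = wrap(tr_gen),
    _["H_av"] = wrap(tr_h),
    _["F_best"] = wrap(tr_best),
    _["F_mean"] = wrap(tr_mean),
    _["final_population"] = final_pop,
    _["zero_fitness_events"] = zero_fitness_events);
}
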