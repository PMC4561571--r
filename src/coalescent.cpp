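// Coalescent simulation of microsatellite (SSR) genotypes under the
// stepwise mutation model.  Two engines share the tree/mutation machinery:
//
//   * cpp_coal_migration -- equilibrium structured coalescent with an
//     arbitrary backward migration-rate matrix (finite island and
//     stepping-stone models);
//   * cpp_coal_scenario  -- event-driven coalescent for demographic
//     scenarios (divergence, size change, admixture), no ongoing migration.
//
// Time is continuous, in generations.  Within a deme holding k lineages of
// size N diploids, coalescence occurs at rate k(k-1)/2 / (2N).  Mutations
// are Poisson on branches, +/-1 repeat with equal probability, reflecting
// at [lo, hi] so that allele sizes stay valid 3-digit Genepop codes.
//
// All randomness comes from R's RNG (RNGScope via Rcpp attributes), so
// set.seed() on the R side makes every simulation reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  // node 0..n_sample-1 are tips (time 0); internal nodes appended in
  // increasing time order, so parent index > child index always holds.
  std::vector<int> parent;
  std::vector<double> time;
  std::vector<int> root_pop; // deme where a root lineage ended (roots only)
  int n_sample;
  double tmrca;
};

inline int reflect(int a, int lo, int hi) {
  while (a < lo || a > hi) {
    if (a < lo) a = 2 * lo - a;
    if (a > hi) a = 2 * hi - a;
  }
  return a;
}

inline int mutate_allele(int a, double len, double mu, int lo, int hi) {
  int nmut = (int) R::rpois(mu * len);
  for (int s = 0; s < nmut; s++) {
    a += (unif_rand() < 0.5) ? -1 : 1;
    a = reflect(a, lo, hi);
  }
  return a;
}

// Drop mutations from the roots down; returns allele size per tip.
std::vector<int> drop_mutations(const Tree &tr, double mu,
                                const std::vector<int> &root_allele,
                                int lo, int hi) {
  int n = (int) tr.parent.size();
  std::vector<int> allele(n);
  for (int id = n - 1; id >= 0; id--) {
    if (tr.parent[id] < 0) {
      allele[id] = root_allele[id];
    } else {
      int p = tr.parent[id];
      allele[id] = mutate_allele(allele[p], tr.time[p] - tr.time[id],
                                 mu, lo, hi);
    }
  }
  allele.resize(tr.n_sample);
  return allele;
}

// Book-keeping for active lineages grouped by deme, with O(1) removal.
struct Demes {
  std::vector< std::vector<int> > mem; // node ids per deme
  explicit Demes(int npop) : mem(npop) {}
  int k(int i) const { return (int) mem[i].size(); }
  int total() const {
    int t = 0;
    for (size_t i = 0; i < mem.size(); i++) t += (int) mem[i].size();
    return t;
  }
  // remove and return a uniformly chosen member of deme i
  int pop_random(int i) {
    int j = (int) (unif_rand() * mem[i].size());
    if (j >= (int) mem[i].size()) j = (int) mem[i].size() - 1;
    int id = mem[i][j];
    mem[i][j] = mem[i].back();
    mem[i].pop_back();
    return id;
  }
};

void do_coalescence(Demes &d, int pop, double t, Tree &tr) {
  int a = d.pop_random(pop);
  int b = d.pop_random(pop);
  int anc = (int) tr.parent.size();
  tr.parent.push_back(-1);
  tr.time.push_back(t);
  tr.parent[a] = anc;
  tr.parent[b] = anc;
  d.mem[pop].push_back(anc);
}

// Equilibrium structured coalescent for one locus.
Tree sim_tree_migration(const IntegerVector &n_ind, double N,
                        const NumericMatrix &mig) {
  int npop = n_ind.size();
  Tree tr;
  tr.n_sample = 0;
  Demes d(npop);
  for (int i = 0; i < npop; i++) {
    for (int j = 0; j < 2 * n_ind[i]; j++) {
      d.mem[i].push_back(tr.n_sample);
      tr.parent.push_back(-1);
      tr.time.push_back(0.0);
      tr.n_sample++;
    }
  }
  std::vector<double> mout(npop, 0.0); // total out-migration rate per lineage
  for (int i = 0; i < npop; i++)
    for (int j = 0; j < npop; j++)
      if (j != i) mout[i] += mig(i, j);

  double t = 0.0;
  while (d.total() > 1) {
    double crate = 0.0, mrate = 0.0;
    for (int i = 0; i < npop; i++) {
      double k = d.k(i);
      crate += k * (k - 1.0) / 2.0 / (2.0 * N);
      mrate += k * mout[i];
    }
    double R = crate + mrate;
    if (R <= 0.0) break; // isolated singletons: multiple roots
    t += exp_rand() / R;
    double u = unif_rand() * R;
    if (u < crate) {
      double acc = 0.0;
      for (int i = 0; i < npop; i++) {
        double k = d.k(i);
        acc += k * (k - 1.0) / 2.0 / (2.0 * N);
        if (u < acc) { do_coalescence(d, i, t, tr); break; }
      }
    } else {
      u -= crate;
      double acc = 0.0;
      int src = npop - 1;
      for (int i = 0; i < npop; i++) {
        acc += d.k(i) * mout[i];
        if (u < acc) { src = i; break; }
      }
      int id = d.pop_random(src);
      double v = unif_rand() * mout[src], acc2 = 0.0;
      int dst = src;
      for (int j = 0; j < npop; j++) {
        if (j == src) continue;
        acc2 += mig(src, j);
        if (v < acc2) { dst = j; break; }
      }
      d.mem[dst].push_back(id);
    }
  }
  tr.tmrca = t;
  tr.root_pop.assign(tr.parent.size(), 0);
  for (int i = 0; i < npop; i++)
    for (size_t j = 0; j < d.mem[i].size(); j++)
      tr.root_pop[d.mem[i][j]] = i;
  return tr;
}

// Coalesce within demes (no migration) until time t_stop or single lineage.
void coalesce_until(Demes &d, const std::vector<double> &size, double &t,
                    double t_stop, Tree &tr) {
  int npop = (int) d.mem.size();
  for (;;) {
    double crate = 0.0;
    for (int i = 0; i < npop; i++) {
      double k = d.k(i);
      crate += k * (k - 1.0) / 2.0 / (2.0 * size[i]);
    }
    if (crate <= 0.0) { if (R_FINITE(t_stop)) t = t_stop; return; }
    double dt = exp_rand() / crate;
    if (t + dt >= t_stop) { t = t_stop; return; }
    t += dt;
    double u = unif_rand() * crate, acc = 0.0;
    for (int i = 0; i < npop; i++) {
      double k = d.k(i);
      acc += k * (k - 1.0) / 2.0 / (2.0 * size[i]);
      if (u < acc) { do_coalescence(d, i, t, tr); break; }
    }
    if (d.total() == 1) return;
  }
}

// Event-driven scenario coalescent for one locus.
// events: columns (time, type, a, b, x), sorted by increasing time.
//   type 0: size change  -- deme a (or all if a < 0) gets size x
//   type 1: merge        -- lineages of deme a move into deme b
//   type 2: admixture    -- each lineage of deme a moves to deme b w.p. x
Tree sim_tree_scenario(const IntegerVector &n_ind,
                       const NumericVector &size0,
                       const NumericMatrix &events) {
  int npop = n_ind.size();
  Tree tr;
  tr.n_sample = 0;
  Demes d(npop);
  for (int i = 0; i < npop; i++) {
    for (int j = 0; j < 2 * n_ind[i]; j++) {
      d.mem[i].push_back(tr.n_sample);
      tr.parent.push_back(-1);
      tr.time.push_back(0.0);
      tr.n_sample++;
    }
  }
  std::vector<double> size(size0.begin(), size0.end());
  double t = 0.0;
  for (int e = 0; e < events.nrow(); e++) {
    double te = events(e, 0);
    coalesce_until(d, size, t, te, tr);
    if (d.total() == 1) break;
    int type = (int) events(e, 1);
    int a = (int) events(e, 2);
    int b = (int) events(e, 3);
    double x = events(e, 4);
    if (type == 0) {
      if (a < 0) for (int i = 0; i < npop; i++) size[i] = x;
      else size[a] = x;
    } else if (type == 1) {
      for (size_t j = 0; j < d.mem[a].size(); j++)
        d.mem[b].push_back(d.mem[a][j]);
      d.mem[a].clear();
    } else if (type == 2) {
      std::vector<int> stay;
      for (size_t j = 0; j < d.mem[a].size(); j++) {
        if (unif_rand() < x) d.mem[b].push_back(d.mem[a][j]);
        else stay.push_back(d.mem[a][j]);
      }
      d.mem[a] = stay;
    }
  }
  if (d.total() > 1) {
    // past the last event: single panmictic ancestral pool in deme 0
    for (int i = 1; i < npop; i++) {
      for (size_t j = 0; j < d.mem[i].size(); j++)
        d.mem[0].push_back(d.mem[i][j]);
      d.mem[i].clear();
    }
    coalesce_until(d, size, t, R_PosInf, tr);
  }
  tr.tmrca = t;
  tr.root_pop.assign(tr.parent.size(), 0);
  return tr;
}

IntegerMatrix collect_genotypes(const IntegerVector &n_ind, int n_loci,
                                double mu, int lo, int hi,
                                const IntegerVector &root_sizes,
                                bool migration_model, double N,
                                const NumericMatrix &mig,
                                const NumericVector &size0,
                                const NumericMatrix &events) {
  int ntot = 0;
  for (int i = 0; i < n_ind.size(); i++) ntot += n_ind[i];
  IntegerMatrix out(ntot, 2 * n_loci);
  NumericVector tmrcas(n_loci);
  for (int l = 0; l < n_loci; l++) {
    Tree tr = migration_model ? sim_tree_migration(n_ind, N, mig)
                              : sim_tree_scenario(n_ind, size0, events);
    std::vector<int> root_allele(tr.parent.size(), 0);
    for (size_t id = 0; id < tr.parent.size(); id++)
      if (tr.parent[id] < 0)
        root_allele[id] = root_sizes[tr.root_pop[id] % root_sizes.size()];
    std::vector<int> allele = drop_mutations(tr, mu, root_allele, lo, hi);
    for (int i = 0; i < ntot; i++) {
      out(i, 2 * l) = allele[2 * i];
      out(i, 2 * l + 1) = allele[2 * i + 1];
    }
    tmrcas[l] = tr.tmrca;
  }
  out.attr("tmrca") = tmrcas;
  return out;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_coal_migration(IntegerVector n_ind, double N,
                                 NumericMatrix mig, double mu, int n_loci,
                                 IntegerVector root_sizes, int lo, int hi) {
  return collect_genotypes(n_ind, n_loci, mu, lo, hi, root_sizes,
                           true, N, mig,
                           NumericVector(0), NumericMatrix(0, 5));
}

// [[Rcpp::export]]
IntegerMatrix cpp_coal_scenario(IntegerVector n_ind, NumericVector size0,
                                NumericMatrix events, double mu, int n_loci,
                                int root_size, int lo, int hi) {
  IntegerVector rs(1);
  rs[0] = root_size;
  return collect_genotypes(n_ind, n_loci, mu, lo, hi, rs,
                           false, 0.0, NumericMatrix(0, 0), size0, events);
}
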