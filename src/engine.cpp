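// Core simulation and LD kernels.
//
// The structured-coalescent engine realizes a hierarchical island model:
// demes nested in groups, lineages co-located in a deme coalesce at rate
// k(k-1)/2, each lineage migrates to another deme of its own group at rate
// M1/2 and to a deme of a different group at rate M2/2 (M are scaled
// migration rates, 2Nm). One locus = one genealogy carrying exactly one
// mutation placed uniformly on total branch length, so every simulated
// locus is polymorphic in the genealogy.
//
// All randomness comes from R's RNG (unif_rand/exp_rand) so set.seed()
// in R makes every simulation reproducible.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  double time;
  int left, right; // children; -1 for leaves
};

// Simulate one genealogy; fill derived[] with per-population derived copy
// counts. Returns total derived count.
int coalesce_one(const std::vector<int> &pop_group,
                 const std::vector<int> &pop_deme,
                 const std::vector<int> &copies,
                 int n_groups, int demes_per_group,
                 double M1, double M2,
                 long max_events,
                 std::vector<int> &derived,
                 std::vector<int> &leaf_is_derived) {
  const int n_pops = (int)copies.size();
  int n_total = 0;
  for (int i = 0; i < n_pops; ++i) n_total += copies[i];

  std::vector<Node> nodes;
  nodes.reserve(2 * n_total);
  std::vector<int> leaf_pop(n_total);

  // active lineages: node index + current deme
  std::vector<int> act_node(n_total), act_deme(n_total);
  {
    int k = 0;
    for (int i = 0; i < n_pops; ++i)
      for (int c = 0; c < copies[i]; ++c) {
        nodes.push_back({0.0, -1, -1});
        leaf_pop[k] = i;
        act_node[k] = k;
        act_deme[k] = pop_deme[i];
        ++k;
      }
  }
  int n_act = n_total;

  // occupancy: flat per-deme lineage counts
  const int n_demes = n_groups * demes_per_group;
  std::vector<int> occ(n_demes, 0);
  for (int k = 0; k < n_act; ++k) occ[act_deme[k]]++;
  double coal_rate = 0.0;
  for (int k = 0; k < n_act; ++k) // sum k(k-1)/2 over occupied demes
    if (occ[act_deme[k]] > 1) coal_rate += (occ[act_deme[k]] - 1.0) / 2.0;

  const double m1 = (demes_per_group > 1) ? M1 / 2.0 : 0.0;
  const double m2 = (n_groups > 1) ? M2 / 2.0 : 0.0;
  const double mig_per_lin = m1 + m2;

  double t = 0.0;
  long events = 0;
  while (n_act > 1) {
    if (++events > max_events)
      stop("structured coalescent exceeded the event cap (%ld); "
           "migration rates may be too large", max_events);
    double tot = coal_rate + n_act * mig_per_lin;
    if (tot <= 0.0)
      stop("zero total event rate with %d lineages in isolated demes; "
           "increase migration rates", n_act);
    t += exp_rand() / tot;
    if (unif_rand() * tot < coal_rate) {
      // coalescence: deme weighted by k(k-1)/2, found by scanning the
      // (few) occupied demes via the active lineages
      double u = unif_rand() * coal_rate, acc = 0.0;
      int deme = -1;
      for (int k = 0; k < n_act; ++k) {
        int d = act_deme[k];
        if (occ[d] > 1) {
          acc += (occ[d] - 1.0) / 2.0; // each of the k lineages adds this
          if (u <= acc) { deme = d; break; }
        }
      }
      if (deme < 0) { // numeric guard
        for (int k = 0; k < n_act; ++k)
          if (occ[act_deme[k]] > 1) { deme = act_deme[k]; break; }
      }
      // pick two distinct lineages in that deme
      std::vector<int> in_deme;
      in_deme.reserve(occ[deme]);
      for (int k = 0; k < n_act; ++k)
        if (act_deme[k] == deme) in_deme.push_back(k);
      int i1 = (int)(unif_rand() * in_deme.size());
      int i2 = (int)(unif_rand() * (in_deme.size() - 1));
      if (i2 >= i1) ++i2;
      int a = in_deme[i1], b = in_deme[i2];
      nodes.push_back({t, act_node[a], act_node[b]});
      int kd = occ[deme];
      coal_rate -= kd - 1.0;
      occ[deme] = kd - 1;
      // replace a with the parent, remove b (swap with last)
      act_node[a] = (int)nodes.size() - 1;
      int last = n_act - 1;
      act_node[b] = act_node[last];
      act_deme[b] = act_deme[last];
      --n_act;
    } else {
      // migration
      int k = (int)(unif_rand() * n_act);
      int old_deme = act_deme[k];
      int g = old_deme / demes_per_group;
      int dest;
      if (unif_rand() * mig_per_lin < m1) {
        int idx = (int)(unif_rand() * (demes_per_group - 1));
        int old_idx = old_deme % demes_per_group;
        if (idx >= old_idx) ++idx;
        dest = g * demes_per_group + idx;
      } else {
        int g2 = (int)(unif_rand() * (n_groups - 1));
        if (g2 >= g) ++g2;
        dest = g2 * demes_per_group + (int)(unif_rand() * demes_per_group);
      }
      coal_rate -= occ[old_deme] - 1.0;
      occ[old_deme]--;
      coal_rate += occ[dest];
      occ[dest]++;
      act_deme[k] = dest;
    }
  }

  // place one mutation uniformly on total branch length
  int n_nodes = (int)nodes.size(); // root = n_nodes - 1
  std::vector<int> parent(n_nodes, -1);
  for (int v = n_total; v < n_nodes; ++v) {
    parent[nodes[v].left] = v;
    parent[nodes[v].right] = v;
  }
  double total_len = 0.0;
  for (int v = 0; v < n_nodes - 1; ++v)
    total_len += nodes[parent[v]].time - nodes[v].time;
  double u = unif_rand() * total_len, acc = 0.0;
  int mut_node = n_nodes - 2;
  for (int v = 0; v < n_nodes - 1; ++v) {
    acc += nodes[parent[v]].time - nodes[v].time;
    if (u <= acc) { mut_node = v; break; }
  }

  // leaves under mut_node carry the derived allele
  std::fill(leaf_is_derived.begin(), leaf_is_derived.end(), 0);
  std::vector<int> stack;
  stack.push_back(mut_node);
  int n_derived = 0;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    if (nodes[v].left < 0) {
      leaf_is_derived[v] = 1;
      ++n_derived;
    } else {
      stack.push_back(nodes[v].left);
      stack.push_back(nodes[v].right);
    }
  }
  std::fill(derived.begin(), derived.end(), 0);
  for (int v = 0; v < n_total; ++v)
    if (leaf_is_derived[v]) derived[leaf_pop[v]]++;
  return n_derived;
}

} // namespace

// [[Rcpp::export(name = ".sim_fdist_batch")]]
List sim_fdist_batch(int n_loci,
                     IntegerVector pop_group,
                     IntegerVector pop_deme,
                     IntegerVector copies,
                     int n_groups, int demes_per_group,
                     double M1, double M2,
                     bool return_genotypes,
                     double max_events) {
  const int n_pops = copies.size();
  std::vector<int> pg(pop_group.begin(), pop_group.end());
  std::vector<int> pd(pop_deme.begin(), pop_deme.end());
  std::vector<int> cp(copies.begin(), copies.end());
  int n_total = 0;
  for (int i = 0; i < n_pops; ++i) n_total += cp[i];
  if (n_total < 2) stop("need at least 2 sampled gene copies");
  for (int i = 0; i < n_pops; ++i)
    if (cp[i] % 2 != 0) stop("gene-copy counts must be even to form diploids");

  RNGScope scope;
  IntegerMatrix derived_mat(n_loci, n_pops);
  IntegerMatrix n00(n_loci, n_pops), n01(n_loci, n_pops), n11(n_loci, n_pops);
  int n_ind = n_total / 2;
  IntegerMatrix geno(return_genotypes ? n_loci : 0, return_genotypes ? n_ind : 0);

  std::vector<int> derived(n_pops), leafder(n_total);
  std::vector<int> offset(n_pops, 0);
  for (int i = 1; i < n_pops; ++i) offset[i] = offset[i - 1] + cp[i - 1];
  std::vector<int> buf;

  for (int l = 0; l < n_loci; ++l) {
    if (l % 256 == 0) checkUserInterrupt();
    coalesce_one(pg, pd, cp, n_groups, demes_per_group, M1, M2,
                 (long)max_events, derived, leafder);
    int ind0 = 0;
    for (int i = 0; i < n_pops; ++i) {
      derived_mat(l, i) = derived[i];
      // random pairing of gene copies into diploids within the deme
      int n = cp[i], d = derived[i];
      buf.assign(n, 0);
      for (int j = 0; j < d; ++j) buf[j] = 1;
      for (int j = n - 1; j > 0; --j) { // Fisher-Yates
        int k = (int)(unif_rand() * (j + 1));
        std::swap(buf[j], buf[k]);
      }
      int c0 = 0, c1 = 0, c2 = 0;
      for (int j = 0; j < n; j += 2) {
        int g = buf[j] + buf[j + 1];
        if (g == 0) ++c0; else if (g == 1) ++c1; else ++c2;
        if (return_genotypes) geno(l, ind0 + j / 2) = g;
      }
      n00(l, i) = c0; n01(l, i) = c1; n11(l, i) = c2;
      ind0 += n / 2;
    }
  }
  List out = List::create(_["derived"] = derived_mat,
                          _["n_hom_ref"] = n00,
                          _["n_het"] = n01,
                          _["n_hom_alt"] = n11);
  if (return_genotypes) out["genotypes"] = geno;
  return out;
}

// EM estimate of two-locus haplotype frequencies from unphased biallelic
// genotypes; only the double heterozygote is phase-ambiguous.
// [[Rcpp::export(name = ".r2_em")]]
NumericVector r2_em(IntegerVector gA, IntegerVector gB,
                    double tol, int max_iter) {
  int n = gA.size();
  double cnt[3][3] = {{0}};
  int used = 0;
  for (int i = 0; i < n; ++i) {
    if (gA[i] == NA_INTEGER || gB[i] == NA_INTEGER) continue;
    cnt[gA[i]][gB[i]] += 1.0;
    ++used;
  }
  if (used < 2) return NumericVector::create(NA_REAL, NA_REAL, used);
  double twoN = 2.0 * used;
  // haplotypes: 11 = alt-alt, 10 = alt-ref, 01 = ref-alt, 00 = ref-ref
  double b11 = 2 * cnt[2][2] + cnt[2][1] + cnt[1][2];
  double b10 = 2 * cnt[2][0] + cnt[2][1] + cnt[1][0];
  double b01 = 2 * cnt[0][2] + cnt[0][1] + cnt[1][2];
  double b00 = 2 * cnt[0][0] + cnt[0][1] + cnt[1][0];
  double ndh = cnt[1][1];
  double pA = (b11 + b10 + ndh) / twoN;
  double pB = (b11 + b01 + ndh) / twoN;
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return NumericVector::create(NA_REAL, NA_REAL, used);
  // EM from several starting p_AB values (the linkage-equilibrium start
  // is a saddle point for some tables, e.g. at allele frequency 1/2);
  // keep the highest-likelihood solution.
  double lo = std::max(0.0, pA + pB - 1), hi = std::min(pA, pB);
  double starts[3] = {pA * pB, lo + 0.01 * (hi - lo), hi - 0.01 * (hi - lo)};
  double best_ll = R_NegInf, best_f11 = pA * pB;
  for (int s = 0; s < 3; ++s) {
    double f11 = starts[s], f10 = pA - f11, f01 = pB - f11,
           f00 = 1 - pA - pB + f11;
    for (int it = 0; it < max_iter; ++it) {
      double denom = f11 * f00 + f10 * f01;
      double c = denom > 0 ? (f11 * f00) / denom : 0.5;
      double n11h = b11 + c * ndh, n00h = b00 + c * ndh;
      double n10h = b10 + (1 - c) * ndh, n01h = b01 + (1 - c) * ndh;
      double g11 = n11h / twoN, g10 = n10h / twoN, g01 = n01h / twoN,
             g00 = n00h / twoN;
      double delta = std::max(std::max(std::abs(g11 - f11),
                                       std::abs(g10 - f10)),
                              std::max(std::abs(g01 - f01),
                                       std::abs(g00 - f00)));
      f11 = g11; f10 = g10; f01 = g01; f00 = g00;
      if (delta < tol) break;
    }
    // multinomial log-likelihood of the genotype table
    double ll = 0;
    ll += b11 * std::log(std::max(f11, 1e-300));
    ll += b10 * std::log(std::max(f10, 1e-300));
    ll += b01 * std::log(std::max(f01, 1e-300));
    ll += b00 * std::log(std::max(f00, 1e-300));
    if (ndh > 0)
      ll += ndh * std::log(std::max(f11 * f00 + f10 * f01, 1e-300));
    if (ll > best_ll) { best_ll = ll; best_f11 = f11; }
  }
  double D = best_f11 - pA * pB;
  double r2 = D * D / (pA * (1 - pA) * pB * (1 - pB));
  return NumericVector::create(r2, D, used);
}
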