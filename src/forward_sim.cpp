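#include <Rcpp.h>
using namespace Rcpp;

// Internally haplotypes are stored as columns of an L x 2N buffer so
// copying one gamete is a contiguous block; the R interface keeps the
// conventional 2N x L (haplotypes in rows) orientation.

static std::vector<int8_t> transpose_in(const IntegerMatrix &H) {
  const int two_n = H.nrow(), L = H.ncol();
  std::vector<int8_t> buf((size_t)two_n * L);
  for (int j = 0; j < L; ++j)
    for (int r = 0; r < two_n; ++r)
      buf[(size_t)r * L + j] = (int8_t)H(r, j);
  return buf;
}

static IntegerMatrix transpose_out(const std::vector<int8_t> &buf, int two_n,
                                   int L) {
  IntegerMatrix H(two_n, L);
  for (int r = 0; r < two_n; ++r)
    for (int j = 0; j < L; ++j)
      H(r, j) = buf[(size_t)r * L + j];
  return H;
}

// build one recombinant gamete into dst from the two parental strands
static void make_gamete(int8_t *dst, const int8_t *a, const int8_t *b,
                        const NumericVector &pos, int L,
                        double region_length, double total_r,
                        double anchor_pos) {
  int nx = (total_r > 0.0) ? R::rpois(total_r) : 0;
  if (nx == 0) {
    std::copy(a, a + L, dst);
    return;
  }
  std::vector<double> bp(nx);
  for (int c = 0; c < nx; ++c) bp[c] = unif_rand() * region_length;
  std::sort(bp.begin(), bp.end());
  // parity of the segment containing the anchor position: the gamete
  // must copy strand `a` there
  int anchor_par = 0;
  for (int c = 0; c < nx; ++c) if (anchor_pos > bp[c]) ++anchor_par;
  anchor_par &= 1;
  int par = 0, c = 0;
  for (int j = 0; j < L; ++j) {
    while (c < nx && pos[j] > bp[c]) { par ^= 1; ++c; }
    dst[j] = (par == anchor_par) ? a[j] : b[j];
  }
}

// Forward Wright-Fisher simulation of a diploid population of phased
// haplotypes with per-generation recombination and viability selection
// at one site (fitness 1, 1+2hs, 1+2s). Uses R's RNG so seeded runs
// are reproducible from R. sel is the 0-based selected column or -1
// for neutral evolution. Returns the final haplotypes, the selected
// allele frequency after each generation (oldest first) and a loss
// flag (the simulation stops early if the selected allele is lost).
// [[Rcpp::export]]
List cpp_wf_forward(IntegerMatrix H, NumericVector pos, double region_length,
                    double total_r, int n_gen, int sel, double s, double h) {
  const int two_n = H.nrow();
  const int n_dip = two_n / 2;
  const int L = H.ncol();
  std::vector<int8_t> cur = transpose_in(H), nxt(cur.size());
  NumericVector traj(sel >= 0 ? n_gen : 0);
  std::vector<double> cum(n_dip);

  for (int g = 0; g < n_gen; ++g) {
    double wtot = 0.0;
    for (int i = 0; i < n_dip; ++i) {
      double wi = 1.0;
      if (sel >= 0 && s > 0.0) {
        int dos = cur[(size_t)(2 * i) * L + sel] +
                  cur[(size_t)(2 * i + 1) * L + sel];
        if (dos == 2) wi = 1.0 + 2.0 * s;
        else if (dos == 1) wi = 1.0 + 2.0 * h * s;
      }
      wtot += wi;
      cum[i] = wtot;
    }
    for (int k = 0; k < two_n; ++k) {
      double u = unif_rand() * wtot;
      int p = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
      if (p >= n_dip) p = n_dip - 1;
      int strand = (unif_rand() < 0.5) ? 0 : 1;
      const int8_t *a = &cur[(size_t)(2 * p + strand) * L];
      const int8_t *b = &cur[(size_t)(2 * p + 1 - strand) * L];
      make_gamete(&nxt[(size_t)k * L], a, b, pos, L, region_length,
                  total_r, pos[0] - 1.0);
    }
    cur.swap(nxt);
    if (sel >= 0) {
      int cnt = 0;
      for (int k = 0; k < two_n; ++k) cnt += cur[(size_t)k * L + sel];
      traj[g] = (double)cnt / two_n;
      if (cnt == 0) {
        return List::create(_["H"] = transpose_out(cur, two_n, L),
                            _["traj"] = traj, _["lost"] = true);
      }
    }
  }
  return List::create(_["H"] = transpose_out(cur, two_n, L),
                      _["traj"] = traj, _["lost"] = false);
}

// EHH walk outward from a core site over one side. carriers are
// 0-based row indices of the core-allele carriers; sites are visited
// in the order given (already outward). Groups of carriers identical
// from the core through the current site are tracked with integer
// relabelling; EHH = sum_g C(n_g,2) / C(n_c,2). Extension stops when
// EHH < trunc (that point is kept) or |pos - core_pos| > max_ext
// (point dropped). Returns the visited site indices (1-based), their
// EHH values, and whether the walk hit the end of the site list while
// still above the truncation threshold.
// [[Rcpp::export]]
List cpp_ehh_walk(IntegerMatrix H, IntegerVector carriers,
                  IntegerVector site_order, NumericVector pos,
                  double core_pos, double trunc, double max_ext) {
  const int n_c = carriers.size();
  const double pairs = (double)n_c * (n_c - 1);
  std::vector<int> g(n_c, 0), g_new(n_c), key(n_c);
  std::vector<int> out_site;
  std::vector<double> out_ehh;
  bool edge = true;
  int n_groups = 1;
  std::vector<int> remap;
  for (int idx = 0; idx < site_order.size(); ++idx) {
    int j = site_order[idx] - 1;
    if (std::fabs(pos[j] - core_pos) > max_ext) break;
    // split groups by the allele at site j
    remap.assign((size_t)n_groups * 2, -1);
    int next_id = 0;
    for (int c = 0; c < n_c; ++c) {
      int k = g[c] * 2 + H(carriers[c], j);
      if (remap[k] < 0) remap[k] = next_id++;
      g_new[c] = remap[k];
    }
    g.swap(g_new);
    n_groups = next_id;
    std::vector<int> cnt(n_groups, 0);
    for (int c = 0; c < n_c; ++c) ++cnt[g[c]];
    double same = 0.0;
    for (int k = 0; k < n_groups; ++k)
      same += (double)cnt[k] * (cnt[k] - 1);
    double e = same / pairs;
    out_site.push_back(j + 1);
    out_ehh.push_back(e);
    if (e < trunc) { edge = false; break; }
  }
  return List::create(_["site"] = wrap(out_site),
                      _["ehh"] = wrap(out_ehh), _["edge"] = edge);
}

// Forward simulation conditioned on a selected-site allele-count path.
// Generation g must end with counts[g] derived gametes at column sel.
// Each offspring gamete is assigned its class first; the strand it
// copies at the selected site is drawn uniformly from the parental
// strands of that class, and the crossover mosaic is anchored there so
// the gamete carries the required allele. Gametes are then placed into
// diploids in random order (random mating).
// [[Rcpp::export]]
List cpp_wf_conditional(IntegerMatrix H, NumericVector pos,
                        double region_length, double total_r,
                        IntegerVector counts, int sel) {
  const int two_n = H.nrow();
  const int L = H.ncol();
  const int n_gen = counts.size();
  const double sel_pos = pos[sel];
  std::vector<int8_t> cur = transpose_in(H), nxt(cur.size());
  std::vector<int> der, anc, perm(two_n);

  for (int g = 0; g < n_gen; ++g) {
    der.clear(); anc.clear();
    for (int r = 0; r < two_n; ++r) {
      if (cur[(size_t)r * L + sel] == 1) der.push_back(r);
      else anc.push_back(r);
    }
    const int k_t = counts[g];
    if ((k_t > 0 && der.empty()) || (k_t < two_n && anc.empty())) {
      return List::create(_["H"] = transpose_out(cur, two_n, L),
                          _["ok"] = false);
    }
    for (int r = 0; r < two_n; ++r) perm[r] = r;
    for (int r = two_n - 1; r > 0; --r) {
      int j = (int)(unif_rand() * (r + 1));
      if (j > r) j = r;
      std::swap(perm[r], perm[j]);
    }
    for (int k = 0; k < two_n; ++k) {
      const std::vector<int> &cls = (k < k_t) ? der : anc;
      int anchor = cls[(int)(unif_rand() * cls.size()) % cls.size()];
      int partner = (anchor % 2 == 0) ? anchor + 1 : anchor - 1;
      make_gamete(&nxt[(size_t)perm[k] * L], &cur[(size_t)anchor * L],
                  &cur[(size_t)partner * L], pos, L, region_length,
                  total_r, sel_pos);
    }
    cur.swap(nxt);
  }
  return List::create(_["H"] = transpose_out(cur, two_n, L),
                      _["ok"] = true);
}
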