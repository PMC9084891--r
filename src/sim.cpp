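// Core lattice engine: elementary updating steps, generations, metrics.
//
// The lattice is a toroidal H x W grid. Each site is Empty, part of a
// Monokaryon (one nucleus) or part of a Dikaryon (nucleus 1 = resident/
// "female" haplotype, nucleus 2 = fertilizing/"male" haplotype). Nuclei
// carry a fitness triple (w_v, w_r, w_m) on the trade-off surface, a
// mating type, an optional DMF allele and a clonal lineage id.
//
// A mycelium (one fungal individual) is a spatially connected set of
// sites carrying the same nuclear lineage multiset. The engine represents
// mycelia as clone records in a registry; sites hold a clone id. Mating
// takeovers ("the winning pair spreads all over the connected parts of
// the affected mycelia") then cost O(1): the affected clones are merged
// under a new record via union-find. Identical nucleotypes in contact
// fuse somatically, and death can split a mycelium in two; both are
// recognised at the generation boundary, when clones are relabelled from
// scratch as exact connected components (a mycelium severed mid-
// generation is treated as one individual until that relabelling).
//
// All randomness is drawn from R's RNG so set.seed() governs the full
// trajectory. Draw order within an elementary step is fixed: site choice
// -> death -> somatic mutation of a visited dikaryon's pair -> mating
// (candidate choice, then di-di resolution or resident choice) ->
// sporulation (Poisson basidium count, then per spore: template choice,
// landing site rejection draws).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Nuc {
  double wv, wr, wm;
  int mt, dmf, lin;
};

struct Spore {
  int site;
  Nuc n;
};

struct Par {
  int scenario;     // 0 diploid, 1 standard, 2 open
  double g, r, d, sigma, beta, lam, theta;
  int disp_radius;
  int dmf_mode;     // 0 off, 1 dominant, 2 codominant, 3 recessive
  bool open_mono_fertilizes_di;
  bool dimon_converts_donor;
  bool spore_blanket;
  int spores_per_basidium;
  double parasite_threshold;
};

// per-generation event tallies (engine telemetry)
struct Events {
  long deaths, colonizations, monmon, dimon, didi, monodi, spores, germs;
  void reset() {
    deaths = colonizations = monmon = dimon = didi = monodi = spores =
      germs = 0;
  }
};

static Par read_par(const List& par) {
  Par p;
  p.scenario = as<int>(par["scenario_code"]);
  p.g = as<double>(par["g"]);
  p.r = as<double>(par["r"]);
  p.d = as<double>(par["d"]);
  p.sigma = as<double>(par["sigma"]);
  p.beta = as<double>(par["beta"]);
  p.lam = as<double>(par["lam"]);
  p.theta = as<double>(par["theta"]);
  p.disp_radius = as<int>(par["disp_radius"]);
  p.dmf_mode = as<int>(par["dmf_mode_code"]);
  p.open_mono_fertilizes_di = as<bool>(par["open_mono_fertilizes_di"]);
  p.dimon_converts_donor = as<bool>(par["dimon_converts_donor"]);
  p.spore_blanket = as<bool>(par["spore_blanket"]);
  p.spores_per_basidium = as<int>(par["spores_per_basidium"]);
  p.parasite_threshold = as<double>(par["parasite_threshold"]);
  return p;
}

// project a clipped non-negative triple back onto the trade-off surface
// sum(w_i^beta) = 1; closed form: scale by c = (sum x_i^beta)^(-1/beta).
static void project_triple(double& wv, double& wr, double& wm, double beta) {
  if (beta == 1.0) {
    double s = wv + wr + wm;
    wv /= s; wr /= s; wm /= s;
  } else {
    double s = std::pow(wv, beta) + std::pow(wr, beta) + std::pow(wm, beta);
    double c = std::pow(s, -1.0 / beta);
    wv *= c; wr *= c; wm *= c;
  }
}

// Gaussian perturbation of each component, negatives clipped at zero,
// all-zero draws retried, then projection back onto the surface.
static void mutate_triple(double& wv, double& wr, double& wm,
                          double sigma, double beta) {
  if (sigma <= 0.0) return;
  double x, y, z;
  do {
    x = wv + norm_rand() * sigma; if (x < 0) x = 0;
    y = wr + norm_rand() * sigma; if (y < 0) y = 0;
    z = wm + norm_rand() * sigma; if (z < 0) z = 0;
  } while (x + y + z <= 0.0);
  wv = x; wr = y; wm = z;
  project_triple(wv, wr, wm, beta);
}

// clone registry record: one living mycelium (or a merged alias)
struct CRec {
  Nuc a, b;
  int kind;    // 1 monokaryon, 2 dikaryon
  int parent;  // -1 if root, else alias of another record (union-find)
};

class Grid {
public:
  int H, W, N;
  std::vector<char> hab;
  std::vector<int> clone;     // registry index per site, -1 if empty
  std::vector<CRec> reg;
  std::vector<int> nb;        // 8 neighbours per site, row-major offsets
  int next_lin;

  int find(int c) {
    int root = c;
    while (reg[root].parent != -1) root = reg[root].parent;
    while (reg[c].parent != -1) {
      int up = reg[c].parent;
      reg[c].parent = root;
      c = up;
    }
    return root;
  }

  inline int state_of(int i) {
    if (clone[i] < 0) return 0;
    return reg[find(clone[i])].kind;
  }
  inline CRec& rec_of(int i) { return reg[find(clone[i])]; }

  Grid(const List& lat) {
    IntegerMatrix st = lat["state"];
    LogicalMatrix hb = lat["habitable"];
    NumericMatrix wv1 = lat["wv1"], wr1 = lat["wr1"], wm1 = lat["wm1"];
    NumericMatrix wv2 = lat["wv2"], wr2 = lat["wr2"], wm2 = lat["wm2"];
    IntegerMatrix mt1 = lat["mt1"], mt2 = lat["mt2"];
    IntegerMatrix df1 = lat["dmf1"], df2 = lat["dmf2"];
    IntegerMatrix ln1 = lat["lin1"], ln2 = lat["lin2"];
    H = st.nrow(); W = st.ncol(); N = H * W;
    hab.resize(N);
    clone.assign(N, -1);
    build_nb();
    next_lin = as<int>(lat["next_lineage"]);
    // group contiguous same-genotype sites into clones (assumes the
    // incoming lattice is clone-homogeneous, as package lattices are)
    std::vector<int> st0(N);
    for (int i = 0; i < N; i++) {
      st0[i] = st[i];
      hab[i] = hb[i] ? 1 : 0;
    }
    std::vector<int> queue;
    for (int i = 0; i < N; i++) {
      if (st0[i] == 0 || clone[i] != -1) continue;
      CRec rec;
      rec.kind = st0[i];
      rec.parent = -1;
      rec.a.wv = wv1[i]; rec.a.wr = wr1[i]; rec.a.wm = wm1[i];
      rec.a.mt = mt1[i]; rec.a.dmf = df1[i]; rec.a.lin = ln1[i];
      if (st0[i] == 2) {
        rec.b.wv = wv2[i]; rec.b.wr = wr2[i]; rec.b.wm = wm2[i];
        rec.b.mt = mt2[i]; rec.b.dmf = df2[i]; rec.b.lin = ln2[i];
      }
      int id = reg.size();
      reg.push_back(rec);
      clone[i] = id;
      queue.clear();
      queue.push_back(i);
      int l1 = ln1[i];
      int l2 = st0[i] == 2 ? (int)ln2[i] : NA_INTEGER;
      while (!queue.empty()) {
        int u = queue.back();
        queue.pop_back();
        for (int k = 0; k < 8; k++) {
          int j = nb[8 * u + k];
          if (clone[j] != -1 || st0[j] != st0[i]) continue;
          bool same;
          if (st0[i] == 1) {
            same = ln1[j] == l1;
          } else {
            int j1 = ln1[j], j2 = ln2[j];
            same = (j1 == l1 && j2 == l2) || (j1 == l2 && j2 == l1);
          }
          if (same) {
            clone[j] = id;
            queue.push_back(j);
          }
        }
      }
    }
  }

  void build_nb() {
    nb.resize(8 * N);
    static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    for (int c = 0; c < W; c++) {
      for (int r = 0; r < H; r++) {
        int i = r + c * H;
        for (int k = 0; k < 8; k++) {
          int r2 = (r + DR[k] + H) % H;
          int c2 = (c + DC[k] + W) % W;
          nb[8 * i + k] = r2 + c2 * H;
        }
      }
    }
  }

  // Exact relabelling: recompute clones as maximal 8-connected components
  // of same-genotype sites. Recognises somatic fusion of identical
  // nucleotypes and death-induced splits, and compacts the registry.
  void relabel() {
    std::vector<CRec> nreg;
    std::vector<int> nclone(N, -1);
    std::vector<int> queue;
    for (int i = 0; i < N; i++) {
      if (clone[i] < 0 || nclone[i] != -1) continue;
      CRec rec = reg[find(clone[i])];
      rec.parent = -1;
      int id = nreg.size();
      nreg.push_back(rec);
      nclone[i] = id;
      queue.clear();
      queue.push_back(i);
      while (!queue.empty()) {
        int u = queue.back();
        queue.pop_back();
        for (int k = 0; k < 8; k++) {
          int j = nb[8 * u + k];
          if (nclone[j] != -1 || clone[j] < 0) continue;
          const CRec& rj = reg[find(clone[j])];
          if (rj.kind != rec.kind) continue;
          bool same;
          if (rec.kind == 1) {
            same = rj.a.lin == rec.a.lin;
          } else {
            same = (rj.a.lin == rec.a.lin && rj.b.lin == rec.b.lin) ||
                   (rj.a.lin == rec.b.lin && rj.b.lin == rec.a.lin);
          }
          if (same) {
            nclone[j] = id;
            queue.push_back(j);
          }
        }
      }
    }
    reg.swap(nreg);
    clone.swap(nclone);
  }

  bool same_genotype(int i, int j) {
    if (clone[i] < 0 || clone[j] < 0) return false;
    if (find(clone[i]) == find(clone[j])) return true;
    const CRec& ri = reg[find(clone[i])];
    const CRec& rj = reg[find(clone[j])];
    if (ri.kind != rj.kind) return false;
    if (ri.kind == 1) return ri.a.lin == rj.a.lin;
    return (ri.a.lin == rj.a.lin && ri.b.lin == rj.b.lin) ||
           (ri.a.lin == rj.b.lin && ri.b.lin == rj.a.lin);
  }

  double veg_rate(const CRec& r, const Par& p) const {
    if (r.kind == 1) return p.g * r.a.wv;
    double hi = r.a.wv > r.b.wv ? r.a.wv : r.b.wv;
    double lo = r.a.wv > r.b.wv ? r.b.wv : r.a.wv;
    return p.g * (hi * p.theta + lo * (1.0 - p.theta));
  }

  double rep_rate(const CRec& r, const Par& p) const {
    if (r.kind != 2) return 0.0;
    double hi = r.a.wr > r.b.wr ? r.a.wr : r.b.wr;
    double lo = r.a.wr > r.b.wr ? r.b.wr : r.a.wr;
    return p.r * (hi * p.theta + lo * (1.0 - p.theta));
  }

  List to_list() {
    IntegerMatrix st(H, W);
    LogicalMatrix hb(H, W);
    NumericMatrix wv1(H, W), wr1(H, W), wm1(H, W);
    NumericMatrix wv2(H, W), wr2(H, W), wm2(H, W);
    IntegerMatrix mt1(H, W), mt2(H, W), df1(H, W), df2(H, W);
    IntegerMatrix ln1(H, W), ln2(H, W);
    std::fill(wv1.begin(), wv1.end(), NA_REAL);
    std::fill(wr1.begin(), wr1.end(), NA_REAL);
    std::fill(wm1.begin(), wm1.end(), NA_REAL);
    std::fill(wv2.begin(), wv2.end(), NA_REAL);
    std::fill(wr2.begin(), wr2.end(), NA_REAL);
    std::fill(wm2.begin(), wm2.end(), NA_REAL);
    std::fill(mt1.begin(), mt1.end(), NA_INTEGER);
    std::fill(mt2.begin(), mt2.end(), NA_INTEGER);
    std::fill(df1.begin(), df1.end(), NA_INTEGER);
    std::fill(df2.begin(), df2.end(), NA_INTEGER);
    std::fill(ln1.begin(), ln1.end(), NA_INTEGER);
    std::fill(ln2.begin(), ln2.end(), NA_INTEGER);
    for (int i = 0; i < N; i++) {
      hb[i] = hab[i] != 0;
      if (clone[i] < 0) {
        st[i] = 0;
        continue;
      }
      const CRec& r = reg[find(clone[i])];
      st[i] = r.kind;
      wv1[i] = r.a.wv; wr1[i] = r.a.wr; wm1[i] = r.a.wm;
      mt1[i] = r.a.mt; df1[i] = r.a.dmf; ln1[i] = r.a.lin;
      if (r.kind == 2) {
        wv2[i] = r.b.wv; wr2[i] = r.b.wr; wm2[i] = r.b.wm;
        mt2[i] = r.b.mt; df2[i] = r.b.dmf; ln2[i] = r.b.lin;
      }
    }
    return List::create(
      _["state"] = st, _["habitable"] = hb,
      _["wv1"] = wv1, _["wr1"] = wr1, _["wm1"] = wm1,
      _["mt1"] = mt1, _["dmf1"] = df1, _["lin1"] = ln1,
      _["wv2"] = wv2, _["wr2"] = wr2, _["wm2"] = wm2,
      _["mt2"] = mt2, _["dmf2"] = df2, _["lin2"] = ln2,
      _["next_lineage"] = next_lin);
  }
};

struct Cand {
  int site;   // source site
  int kind;   // 1 from monokaryon, 2 from dikaryon
  int which;  // which nucleus at the source (1 or 2)
  Nuc n;
};

// Candidate "male" nuclei around a focal site, one entry per compatible
// nucleus per neighbouring site (a mycelium spanning several neighbour
// sites competes once per contact site). Sites identical in genotype to
// the focal mycelium are not mates: they are the same individual
// (somatic fusion).
static void list_cands(Grid& G, const Par& p, int focal,
                       std::vector<Cand>& out) {
  out.clear();
  CRec& fr = G.rec_of(focal);
  bool focal_mono = fr.kind == 1;
  int fmt1 = fr.a.mt;
  for (int k = 0; k < 8; k++) {
    int j = G.nb[8 * focal + k];
    if (G.clone[j] < 0) continue;
    if (G.same_genotype(focal, j)) continue;
    CRec& rj = G.rec_of(j);
    if (focal_mono) {
      if (rj.kind == 1) {
        if (rj.a.mt != fmt1) {
          Cand c; c.site = j; c.kind = 1; c.which = 1; c.n = rj.a;
          out.push_back(c);
        }
      } else if (p.scenario >= 1) {  // di-mon: standard and open only
        bool elig1 = true, elig2 = true;
        if (p.dmf_mode == 1) {             // dominant
          bool any = rj.a.dmf || rj.b.dmf;
          elig1 = any; elig2 = any;
        } else if (p.dmf_mode == 2) {      // codominant
          elig1 = rj.a.dmf != 0; elig2 = rj.b.dmf != 0;
        } else if (p.dmf_mode == 3) {      // recessive
          bool both = rj.a.dmf && rj.b.dmf;
          elig1 = both; elig2 = both;
        }
        if (elig1 && rj.a.mt != fmt1) {
          Cand c; c.site = j; c.kind = 2; c.which = 1; c.n = rj.a;
          out.push_back(c);
        }
        if (elig2 && rj.b.mt != fmt1) {
          Cand c; c.site = j; c.kind = 2; c.which = 2; c.n = rj.b;
          out.push_back(c);
        }
      }
    } else {
      // focal dikaryon: open scenario only (checked by caller)
      if (rj.kind == 2) {
        // any donor nucleus is compatible with at least one resident
        Cand c1; c1.site = j; c1.kind = 2; c1.which = 1; c1.n = rj.a;
        Cand c2; c2.site = j; c2.kind = 2; c2.which = 2; c2.n = rj.b;
        out.push_back(c1);
        out.push_back(c2);
      } else if (p.open_mono_fertilizes_di) {
        Cand c; c.site = j; c.kind = 1; c.which = 1; c.n = rj.a;
        out.push_back(c);
      }
    }
  }
}

// choose index with probability w_m / sum(w_m); uniform if all weights zero
static int weighted_pick(const std::vector<double>& w) {
  double tot = 0.0;
  for (size_t i = 0; i < w.size(); i++) tot += w[i];
  if (tot <= 0.0) {
    int k = (int)(unif_rand() * w.size());
    if (k >= (int)w.size()) k = w.size() - 1;
    return k;
  }
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); i++) {
    acc += w[i];
    if (u < acc) return i;
  }
  return w.size() - 1;
}

// merge the clones at `f` and (optionally) `d` under a fresh dikaryon
// record carrying the winning pair
static void takeover(Grid& G, int f, int d, const Nuc& n1, const Nuc& n2) {
  CRec rec;
  rec.a = n1;
  rec.b = n2;
  rec.kind = 2;
  rec.parent = -1;
  int id = G.reg.size();
  G.reg.push_back(rec);
  G.reg[G.find(G.clone[f])].parent = id;
  if (d >= 0) {
    int rd = G.find(G.clone[d]);
    if (rd != id) G.reg[rd].parent = id;
  }
}

// Mating attempt with `focal` in the female role. Returns true if the
// lattice changed.
static bool attempt_mating(Grid& G, const Par& p, int focal,
                           std::vector<Cand>& cbuf, Events& ev) {
  CRec& fr = G.rec_of(focal);
  bool focal_mono = fr.kind == 1;
  if (!focal_mono && p.scenario != 2) return false;
  list_cands(G, p, focal, cbuf);
  if (cbuf.empty()) return false;
  std::vector<double> w(cbuf.size());
  for (size_t i = 0; i < cbuf.size(); i++) w[i] = cbuf[i].n.wm;
  const Cand& win = cbuf[weighted_pick(w)];

  if (focal_mono) {
    Nuc n1 = fr.a;
    Nuc n2 = win.n;
    if (win.kind == 1) {
      // mon-mon: both mycelia become the new dikaryon
      ev.monmon++;
      takeover(G, focal, win.site, n1, n2);
    } else if (p.dimon_converts_donor) {
      // di-mon: the winning pair spreads over both affected mycelia,
      // evicting the donor's losing partner nucleus from its territory
      ev.dimon++;
      takeover(G, focal, win.site, n1, n2);
    } else {
      // di-mon, strict Buller reading: donor dikaryon unchanged
      ev.dimon++;
      takeover(G, focal, -1, n1, n2);
    }
    return true;
  }

  // focal dikaryon, open scenario
  if (win.kind == 2) {
    // di-di: the four nuclei compete in mating-type-compatible pairs,
    // pair {i,j} weighted by w_m(i) * w_m(j)
    CRec& dr = G.rec_of(win.site);
    Nuc four[4] = {fr.a, fr.b, dr.a, dr.b};
    std::vector<std::pair<int, int> > pairs;
    std::vector<double> pw;
    for (int i = 0; i < 4; i++)
      for (int j = i + 1; j < 4; j++)
        if (four[i].mt != four[j].mt) {
          pairs.push_back(std::make_pair(i, j));
          pw.push_back(four[i].wm * four[j].wm);
        }
    if (pairs.empty()) return false;
    int k = weighted_pick(pw);
    int pi = pairs[k].first, pj = pairs[k].second;
    if (pi == 0 && pj == 1) return false;  // focal pair retained: no-op
    Nuc n1, n2;
    if (pi <= 1) { n1 = four[pi]; n2 = four[pj]; }  // focal keeps female role
    else if (unif_rand() < 0.5) { n1 = four[pi]; n2 = four[pj]; }
    else { n1 = four[pj]; n2 = four[pi]; }
    ev.didi++;
    takeover(G, focal, win.site, n1, n2);
    return true;
  }

  // monokaryon nucleus fertilizes the focal dikaryon: one resident is
  // displaced; the retained resident is chosen among compatible residents
  // with probability proportional to w_m
  Nuc inc = win.n;
  bool ok1 = fr.a.mt != inc.mt;
  bool ok2 = fr.b.mt != inc.mt;
  if (!ok1 && !ok2) return false;
  Nuc kept;
  if (ok1 && ok2) {
    std::vector<double> rw(2);
    rw[0] = fr.a.wm; rw[1] = fr.b.wm;
    kept = weighted_pick(rw) == 0 ? fr.a : fr.b;
  } else {
    kept = ok1 ? fr.a : fr.b;
  }
  ev.monodi++;
  takeover(G, focal, win.site, kept, inc);
  return true;
}

// meiotic spore from the two nuclei of a dikaryon: blend the (already
// mutated, see step_at) parental triples by lambda towards a uniformly
// chosen template parent, re-project; mating type and DMF travel with
// the template (linkage)
static Nuc make_spore_nuc(const CRec& r, const Par& p, int lin) {
  const Nuc& tpl = (unif_rand() < 0.5) ? r.a : r.b;
  Nuc sp;
  sp.wv = p.lam * tpl.wv + (1.0 - p.lam) * 0.5 * (r.a.wv + r.b.wv);
  sp.wr = p.lam * tpl.wr + (1.0 - p.lam) * 0.5 * (r.a.wr + r.b.wr);
  sp.wm = p.lam * tpl.wm + (1.0 - p.lam) * 0.5 * (r.a.wm + r.b.wm);
  project_triple(sp.wv, sp.wr, sp.wm, p.beta);
  sp.mt = tpl.mt;
  sp.dmf = tpl.dmf;
  sp.lin = lin;
  return sp;
}

static void sporulate(Grid& G, const Par& p, int idx,
                      std::vector<Spore>& bank, Events& ev) {
  CRec& r = G.rec_of(idx);
  double rate = G.rep_rate(r, p);
  if (rate <= 0.0) return;
  int r0 = idx % G.H, c0 = idx / G.H;
  if (p.spore_blanket) {
    // alternative fecundity reading: sporulation fires with probability
    // r * W_r and showers one spore onto every site within the radius
    if (unif_rand() >= rate) return;
    for (int dr = -p.disp_radius; dr <= p.disp_radius; dr++) {
      for (int dc = -p.disp_radius; dc <= p.disp_radius; dc++) {
        if (dr == 0 && dc == 0) continue;
        Spore sp;
        sp.n = make_spore_nuc(r, p, G.next_lin++);
        int r2 = ((r0 + dr) % G.H + G.H) % G.H;
        int c2 = ((c0 + dc) % G.W + G.W) % G.W;
        sp.site = r2 + c2 * G.H;
        bank.push_back(sp);
        ev.spores++;
      }
    }
    return;
  }
  // each basidium releases a tetrad of independent meiotic spores
  int k = (int)R::rpois(rate) * p.spores_per_basidium;
  ev.spores += k;
  int side = 2 * p.disp_radius + 1;
  for (int s = 0; s < k; s++) {
    Spore sp;
    sp.n = make_spore_nuc(r, p, G.next_lin++);
    int dr, dc;
    do {
      dr = (int)(unif_rand() * side) - p.disp_radius;
      dc = (int)(unif_rand() * side) - p.disp_radius;
    } while (dr == 0 && dc == 0);
    int r2 = ((r0 + dr) % G.H + G.H) % G.H;
    int c2 = ((c0 + dc) % G.W + G.W) % G.W;
    sp.site = r2 + c2 * G.H;
    bank.push_back(sp);
  }
}

static void colonize(Grid& G, const Par& p, int idx, Events& ev) {
  int winners[8];
  double rates[8];
  int nw = 0;
  for (int k = 0; k < 8; k++) {
    int j = G.nb[8 * idx + k];
    if (G.clone[j] < 0) continue;
    double rate = G.veg_rate(G.rec_of(j), p);
    if (unif_rand() < rate) {
      winners[nw] = j;
      rates[nw] = rate;
      nw++;
    }
  }
  if (nw == 0) return;
  int k = 0;
  if (nw > 1) {
    std::vector<double> w(rates, rates + nw);
    k = weighted_pick(w);
  }
  ev.colonizations++;
  G.clone[idx] = G.clone[winners[k]];
}

// One elementary updating step at `idx` (caller chooses the site).
// Occupied: death with probability d, else somatic mutation (dikaryons),
// mating in the female role, then sporulation if (still) dikaryotic.
// Empty habitable: colonization.
static void step_at(Grid& G, const Par& p, int idx,
                    std::vector<Spore>& bank,
                    std::vector<Cand>& cbuf, Events& ev) {
  if (G.clone[idx] >= 0) {
    if (unif_rand() < p.d) {
      G.clone[idx] = -1;
      ev.deaths++;
      return;
    }
    CRec& r = G.rec_of(idx);
    if (r.kind == 2) {
      // somatic mutation during the dikaryotic state: the resident pair
      // of this mycelium takes one Gaussian step before mating/meiosis
      mutate_triple(r.a.wv, r.a.wr, r.a.wm, p.sigma, p.beta);
      mutate_triple(r.b.wv, r.b.wr, r.b.wm, p.sigma, p.beta);
    }
    attempt_mating(G, p, idx, cbuf, ev);
    if (G.rec_of(idx).kind == 2) sporulate(G, p, idx, bank, ev);
  } else if (G.hab[idx]) {
    colonize(G, p, idx, ev);
  }
}

// One spore per empty habitable site survives, chosen uniformly among the
// spores that landed there (single-pass reservoir); the bank is cleared.
static void germinate(Grid& G, const std::vector<Spore>& bank,
                      Events& ev) {
  if (bank.empty()) return;
  std::vector<int> cnt(G.N, 0);
  std::vector<Nuc> chosen(G.N);
  std::vector<int> touched;
  for (size_t i = 0; i < bank.size(); i++) {
    int s = bank[i].site;
    if (cnt[s] == 0) touched.push_back(s);
    cnt[s]++;
    if (unif_rand() < 1.0 / cnt[s]) chosen[s] = bank[i].n;
  }
  for (size_t t = 0; t < touched.size(); t++) {
    int s = touched[t];
    if (G.clone[s] < 0 && G.hab[s]) {
      CRec rec;
      rec.a = chosen[s];
      rec.kind = 1;
      rec.parent = -1;
      G.clone[s] = G.reg.size();
      G.reg.push_back(rec);
      ev.germs++;
    }
  }
}

// per-generation census; 20 columns, NA where the denominator is zero
static void summarize_into(Grid& G, const Par& p, double* row) {
  int n_mono = 0, n_di = 0;
  double sv_m = 0, sr_m = 0, sm_m = 0;
  double sv_1 = 0, sr_1 = 0, sm_1 = 0;
  double sv_2 = 0, sr_2 = 0, sm_2 = 0;
  int para_m = 0, para_1 = 0, para_2 = 0;
  int dmf_m = 0, dmf_1 = 0, dmf_2 = 0;
  for (int i = 0; i < G.N; i++) {
    if (G.clone[i] < 0) continue;
    const CRec& r = G.reg[G.find(G.clone[i])];
    if (r.kind == 1) {
      n_mono++;
      sv_m += r.a.wv; sr_m += r.a.wr; sm_m += r.a.wm;
      if (r.a.wm > p.parasite_threshold) para_m++;
      if (r.a.dmf) dmf_m++;
    } else {
      n_di++;
      sv_1 += r.a.wv; sr_1 += r.a.wr; sm_1 += r.a.wm;
      sv_2 += r.b.wv; sr_2 += r.b.wr; sm_2 += r.b.wm;
      if (r.a.wm > p.parasite_threshold) para_1++;
      if (r.b.wm > p.parasite_threshold) para_2++;
      if (r.a.dmf) dmf_1++;
      if (r.b.dmf) dmf_2++;
    }
  }
  int pop = n_mono + n_di;
  int nuclei = n_mono + 2 * n_di;
  row[0] = pop;
  row[1] = n_mono;
  row[2] = n_di;
  row[3] = pop > 0 ? (double)n_di / pop : NA_REAL;
  row[4] = n_mono > 0 ? sv_m / n_mono : NA_REAL;
  row[5] = n_mono > 0 ? sr_m / n_mono : NA_REAL;
  row[6] = n_mono > 0 ? sm_m / n_mono : NA_REAL;
  row[7] = n_di > 0 ? sv_1 / n_di : NA_REAL;
  row[8] = n_di > 0 ? sr_1 / n_di : NA_REAL;
  row[9] = n_di > 0 ? sm_1 / n_di : NA_REAL;
  row[10] = n_di > 0 ? sv_2 / n_di : NA_REAL;
  row[11] = n_di > 0 ? sr_2 / n_di : NA_REAL;
  row[12] = n_di > 0 ? sm_2 / n_di : NA_REAL;
  row[13] = nuclei > 0 ? (double)(para_m + para_1 + para_2) / nuclei : NA_REAL;
  row[14] = n_mono > 0 ? (double)para_m / n_mono : NA_REAL;
  row[15] = n_di > 0 ? (double)para_1 / n_di : NA_REAL;
  row[16] = n_di > 0 ? (double)para_2 / n_di : NA_REAL;
  row[17] = n_mono > 0 ? (double)dmf_m / n_mono : NA_REAL;
  row[18] = n_di > 0 ? (double)dmf_1 / n_di : NA_REAL;
  row[19] = n_di > 0 ? (double)dmf_2 / n_di : NA_REAL;
}

static DataFrame bank_to_df(const std::vector<Spore>& bank) {
  int n = bank.size();
  IntegerVector site(n), mt(n), dmf(n), lin(n);
  NumericVector wv(n), wr(n), wm(n);
  for (int i = 0; i < n; i++) {
    site[i] = bank[i].site + 1;
    wv[i] = bank[i].n.wv; wr[i] = bank[i].n.wr; wm[i] = bank[i].n.wm;
    mt[i] = bank[i].n.mt; dmf[i] = bank[i].n.dmf; lin[i] = bank[i].n.lin;
  }
  return DataFrame::create(
    _["site"] = site, _["wv"] = wv, _["wr"] = wr, _["wm"] = wm,
    _["mt"] = mt, _["dmf"] = dmf, _["lin"] = lin);
}

static void df_to_bank(const DataFrame& df, std::vector<Spore>& bank) {
  IntegerVector site = df["site"], mt = df["mt"], dmf = df["dmf"],
                lin = df["lin"];
  NumericVector wv = df["wv"], wr = df["wr"], wm = df["wm"];
  for (int i = 0; i < site.size(); i++) {
    Spore s;
    s.site = site[i] - 1;
    s.n.wv = wv[i]; s.n.wr = wr[i]; s.n.wm = wm[i];
    s.n.mt = mt[i]; s.n.dmf = dmf[i]; s.n.lin = lin[i];
    bank.push_back(s);
  }
}

// [[Rcpp::export(name = ".cpp_run_sim")]]
List cpp_run_sim(List lat, List par, int n_generations) {
  Grid G(lat);
  Par p = read_par(par);
  std::vector<Spore> bank;
  std::vector<Cand> cbuf;
  NumericMatrix metrics(n_generations, 20);
  NumericMatrix events(n_generations, 8);
  int extinct_gen = NA_INTEGER;
  double row[20];
  Events ev;
  for (int gen = 0; gen < n_generations; gen++) {
    ev.reset();
    bool alive = false;
    for (int i = 0; i < G.N && !alive; i++) alive = G.clone[i] >= 0;
    if (!alive && bank.empty()) {
      // extinct and no spores left: nothing can happen any more
      if (extinct_gen == NA_INTEGER) extinct_gen = gen;
      summarize_into(G, p, row);
      for (int c = 0; c < 20; c++) metrics(gen, c) = row[c];
      continue;
    }
    for (int s = 0; s < G.N; s++) {
      int idx = (int)(unif_rand() * G.N);
      if (idx >= G.N) idx = G.N - 1;
      step_at(G, p, idx, bank, cbuf, ev);
    }
    // census first: spores banked this generation germinate into the
    // next one, so fresh monokaryons are not counted before they have
    // had a single mating opportunity
    G.relabel();
    summarize_into(G, p, row);
    for (int c = 0; c < 20; c++) metrics(gen, c) = row[c];
    germinate(G, bank, ev);
    bank.clear();
    events(gen, 0) = ev.deaths;
    events(gen, 1) = ev.colonizations;
    events(gen, 2) = ev.monmon;
    events(gen, 3) = ev.dimon;
    events(gen, 4) = ev.didi;
    events(gen, 5) = ev.monodi;
    events(gen, 6) = ev.spores;
    events(gen, 7) = ev.germs;
  }
  return List::create(
    _["lattice"] = G.to_list(),
    _["metrics"] = metrics,
    _["events"] = events,
    _["extinct_gen"] = extinct_gen);
}

// [[Rcpp::export(name = ".cpp_step_at")]]
List cpp_step_at(List lat, List par, int site) {
  Grid G(lat);
  Par p = read_par(par);
  std::vector<Spore> bank;
  std::vector<Cand> cbuf;
  Events ev;
  ev.reset();
  int idx;
  if (site <= 0) {
    idx = (int)(unif_rand() * G.N);
    if (idx >= G.N) idx = G.N - 1;
  } else {
    idx = site - 1;
  }
  step_at(G, p, idx, bank, cbuf, ev);
  G.relabel();
  return List::create(
    _["lattice"] = G.to_list(),
    _["spores"] = bank_to_df(bank),
    _["site"] = idx + 1);
}

// [[Rcpp::export(name = ".cpp_germinate")]]
List cpp_germinate(List lat, DataFrame spores) {
  Grid G(lat);
  std::vector<Spore> bank;
  df_to_bank(spores, bank);
  Events ev;
  ev.reset();
  germinate(G, bank, ev);
  G.relabel();
  return G.to_list();
}

// [[Rcpp::export(name = ".cpp_summarize")]]
NumericVector cpp_summarize(List lat, List par) {
  Grid G(lat);
  Par p = read_par(par);
  NumericVector row(20);
  double buf[20];
  summarize_into(G, p, buf);
  for (int i = 0; i < 20; i++) row[i] = buf[i];
  return row;
}

// [[Rcpp::export(name = ".cpp_mycelium_of")]]
IntegerVector cpp_mycelium_of(List lat, int site) {
  Grid G(lat);
  if (site < 1 || site > G.N) stop("invalid site index");
  if (G.clone[site - 1] < 0) stop("empty site has no mycelium");
  // exact connected component around `site` (fresh BFS, ignores registry)
  std::vector<int> comp;
  std::vector<char> seen(G.N, 0);
  std::vector<int> queue;
  queue.push_back(site - 1);
  seen[site - 1] = 1;
  while (!queue.empty()) {
    int u = queue.back();
    queue.pop_back();
    comp.push_back(u);
    for (int k = 0; k < 8; k++) {
      int j = G.nb[8 * u + k];
      if (!seen[j] && G.clone[j] >= 0 && G.same_genotype(site - 1, j)) {
        seen[j] = 1;
        queue.push_back(j);
      }
    }
  }
  IntegerVector out(comp.size());
  for (size_t i = 0; i < comp.size(); i++) out[i] = comp[i] + 1;
  std::sort(out.begin(), out.end());
  return out;
}
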