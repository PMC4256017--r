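// Cellular Potts engine: lattice + agent bookkeeping, Metropolis pixel-copy
// dynamics against an effective energy with contact-adhesion, volume,
// surface and center-of-mass spring (focal point plasticity) terms, plus
// the per-MCS death rules (crowding-gated apoptosis, distance-gated
// necrosis) that run inside the inner loop.
//
// Conventions:
//  - lattice sigma is an integer matrix, first dimension x, second y;
//    sigma = 0 is culture medium; the one-pixel boundary frame is
//    immutable medium (never a copy target).
//  - agent types: 0 medium, 1 LEP, 2 MEP, 3 necrotic.
//  - contact adhesion and the surface count S both use first-order
//    (4-neighbor) pixel faces (the platform convention for the contact
//    and surface terms); copy-attempt sources are drawn from the
//    8-neighborhood of the target pixel.
//  - all coordinates exchanged with R are 1-based; internally 0-based.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

enum CellType { T_MEDIUM = 0, T_LEP = 1, T_MEP = 2, T_NECROTIC = 3 };
// status: 0 unused slot, 1 active, 2 annihilated by dynamics (V reached 0;
// keeps contributing lambda_V*Vt^2 + lambda_S*St^2 so that incremental
// delta-H stays the exact difference of total energies), 3 removed by rule
// (apoptosis; no energy contribution).
enum AgentStatus { S_FREE = 0, S_ACTIVE = 1, S_ANNIHILATED = 2, S_REMOVED = 3 };

struct Link {
  int a, b;
  double lambda, L;
};

struct CPM {
  int W, H;
  std::vector<int> sigma;           // W*H, index x + y*W
  std::vector<int> type;            // per agent slot, index = sigma
  std::vector<int> status;
  std::vector<double> V, S, Vt, St, lamV, lamS, sumx, sumy;
  std::vector<char> prot;           // apoptosis-protected
  std::vector<Link> links;
  double J[4][4];                   // contact energy per unit face
  double fppLam[4][4], fppL[4][4];  // spring parameters by type pair
  double Tm;
  double linkRange;                 // capture range for new spring links

  inline int at(int x, int y) const { return sigma[x + y * W]; }
  inline void set(int x, int y, int s) { sigma[x + y * W] = s; }
  inline bool is_cell(int s) const { return s > 0 && status[s] == S_ACTIVE; }
  inline double comx(int s) const { return sumx[s] / V[s]; }
  inline double comy(int s) const { return sumy[s] / V[s]; }
};

static const int DX8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
static const int DY8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
static const int DX4[4] = {1, -1, 0, 0};
static const int DY4[4] = {0, 0, 1, -1};

static inline double sq(double v) { return v * v; }

static void zero_inert_rows(double M[4][4]) {
  // medium and necrotic agents neither adhere nor pull on partners
  for (int t = 0; t < 4; ++t) {
    M[T_MEDIUM][t] = M[t][T_MEDIUM] = 0.0;
    M[T_NECROTIC][t] = M[t][T_NECROTIC] = 0.0;
  }
}

// [[Rcpp::export]]
SEXP cpm_create(IntegerMatrix lattice, DataFrame agents, NumericMatrix J,
                NumericMatrix fpp_lambda, NumericMatrix fpp_L, double Tm,
                double link_range) {
  CPM* m = new CPM();
  m->W = lattice.nrow();
  m->H = lattice.ncol();
  m->Tm = Tm;
  m->linkRange = link_range;
  m->sigma.assign(lattice.begin(), lattice.end());

  IntegerVector sig = agents["sigma"];
  IntegerVector typ = agents["type"];
  NumericVector vt = agents["Vt"], st = agents["St"], lv = agents["lambda_V"],
                ls = agents["lambda_S"];
  int maxsig = 0;
  for (int i = 0; i < sig.size(); ++i) maxsig = std::max(maxsig, sig[i]);
  for (size_t i = 0; i < m->sigma.size(); ++i)
    if (m->sigma[i] > maxsig)
      stop("lattice contains an unregistered agent index");
  int n = maxsig + 1;
  m->type.assign(n, T_MEDIUM);
  m->status.assign(n, S_FREE);
  m->V.assign(n, 0.0); m->S.assign(n, 0.0);
  m->Vt.assign(n, 0.0); m->St.assign(n, 0.0);
  m->lamV.assign(n, 0.0); m->lamS.assign(n, 0.0);
  m->sumx.assign(n, 0.0); m->sumy.assign(n, 0.0);
  m->prot.assign(n, 0);
  for (int i = 0; i < sig.size(); ++i) {
    int s = sig[i];
    if (s <= 0) stop("agent indices must be positive");
    m->type[s] = typ[i];
    m->status[s] = S_ACTIVE;
    m->Vt[s] = vt[i]; m->St[s] = st[i];
    m->lamV[s] = lv[i]; m->lamS[s] = ls[i];
  }
  // volume, surface, center-of-mass from the lattice
  for (int y = 0; y < m->H; ++y)
    for (int x = 0; x < m->W; ++x) {
      int s = m->at(x, y);
      if (s == 0) continue;
      if (m->status[s] != S_ACTIVE) stop("lattice contains an unregistered agent index");
      m->V[s] += 1; m->sumx[s] += x; m->sumy[s] += y;
      for (int k = 0; k < 4; ++k) {
        int nx = x + DX4[k], ny = y + DY4[k];
        int u = (nx < 0 || ny < 0 || nx >= m->W || ny >= m->H) ? 0 : m->at(nx, ny);
        if (u != s) m->S[s] += 1;
      }
    }
  for (int i = 0; i < sig.size(); ++i)
    if (m->V[sig[i]] == 0)
      stop("registered agent has no pixels on the lattice");
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) {
      m->J[a][b] = J(a, b);
      m->fppLam[a][b] = fpp_lambda(a, b);
      m->fppL[a][b] = fpp_L(a, b);
    }
  zero_inert_rows(m->J);
  zero_inert_rows(m->fppLam);
  XPtr<CPM> p(m, true);
  return p;
}

// ---------------------------------------------------------------- energies

static double link_energy(const CPM* m, const Link& lk) {
  double dx = m->comx(lk.a) - m->comx(lk.b);
  double dy = m->comy(lk.a) - m->comy(lk.b);
  double l = std::sqrt(dx * dx + dy * dy);
  return lk.lambda * sq(l - lk.L);
}

// [[Rcpp::export]]
double cpm_total_energy(SEXP ptr) {
  XPtr<CPM> m(ptr);
  double E = 0.0;
  for (int y = 0; y < m->H; ++y)
    for (int x = 0; x < m->W; ++x) {
      int s = m->at(x, y);
      if (x + 1 < m->W) {
        int u = m->at(x + 1, y);
        if (u != s) E += m->J[m->type[s]][m->type[u]];
      }
      if (y + 1 < m->H) {
        int u = m->at(x, y + 1);
        if (u != s) E += m->J[m->type[s]][m->type[u]];
      }
    }
  for (size_t s = 1; s < m->V.size(); ++s) {
    if (m->status[s] == S_ACTIVE)
      E += m->lamV[s] * sq(m->V[s] - m->Vt[s]) + m->lamS[s] * sq(m->S[s] - m->St[s]);
    else if (m->status[s] == S_ANNIHILATED)
      E += m->lamV[s] * sq(m->Vt[s]) + m->lamS[s] * sq(m->St[s]);
  }
  for (const Link& lk : m->links) E += link_energy(m, lk);
  return E;
}

// exact incremental change in total energy if pixel (x,y) were overwritten
// with index src (0-based coords)
static double delta_energy_raw(const CPM* m, int x, int y, int src) {
  int cur = m->at(x, y);
  if (cur == src) return 0.0;
  double dE = 0.0;
  int tc = m->type[cur], ts = m->type[src];

  // adhesion over the 4-neighborhood faces of (x,y)
  for (int k = 0; k < 4; ++k) {
    int nx = x + DX4[k], ny = y + DY4[k];
    int u = (nx < 0 || ny < 0 || nx >= m->W || ny >= m->H) ? 0 : m->at(nx, ny);
    int tu = m->type[u];
    if (u != cur) dE -= m->J[tc][tu];
    if (u != src) dE += m->J[ts][tu];
  }

  // volume terms
  if (cur > 0) dE += m->lamV[cur] * (sq(m->V[cur] - 1 - m->Vt[cur]) - sq(m->V[cur] - m->Vt[cur]));
  if (src > 0) dE += m->lamV[src] * (sq(m->V[src] + 1 - m->Vt[src]) - sq(m->V[src] + m->Vt[src] * 0 - m->Vt[src]));

  // surface terms: collect dS per affected agent (cur, src, 4 neighbors)
  int ags[6]; double dS[6]; int na = 0;
  auto addS = [&](int a, double d) {
    if (a == 0) return;
    for (int i = 0; i < na; ++i)
      if (ags[i] == a) { dS[i] += d; return; }
    ags[na] = a; dS[na] = d; ++na;
  };
  for (int k = 0; k < 4; ++k) {
    int nx = x + DX4[k], ny = y + DY4[k];
    int u = (nx < 0 || ny < 0 || nx >= m->W || ny >= m->H) ? 0 : m->at(nx, ny);
    if (cur > 0) addS(cur, -(u != cur ? 1.0 : 0.0));
    if (src > 0) addS(src, (u != src ? 1.0 : 0.0));
    if (u > 0) addS(u, (u != src ? 1.0 : 0.0) - (u != cur ? 1.0 : 0.0));
  }
  for (int i = 0; i < na; ++i) {
    int a = ags[i];
    dE += m->lamS[a] * (sq(m->S[a] + dS[i] - m->St[a]) - sq(m->S[a] - m->St[a]));
  }

  // spring links attached to cur or src: centers of mass move
  bool cur_dies = (cur > 0 && m->V[cur] == 1);
  double cxo = 0, cyo = 0, cxn = 0, cyn = 0, sxo = 0, syo = 0, sxn = 0, syn = 0;
  if (cur > 0) {
    cxo = m->comx(cur); cyo = m->comy(cur);
    if (!cur_dies) {
      cxn = (m->sumx[cur] - x) / (m->V[cur] - 1);
      cyn = (m->sumy[cur] - y) / (m->V[cur] - 1);
    }
  }
  if (src > 0) {
    sxo = m->comx(src); syo = m->comy(src);
    sxn = (m->sumx[src] + x) / (m->V[src] + 1);
    syn = (m->sumy[src] + y) / (m->V[src] + 1);
  }
  for (const Link& lk : m->links) {
    bool ha = (lk.a == cur || lk.b == cur), hs = (lk.a == src || lk.b == src);
    if (!ha && !hs) continue;
    double ax = m->comx(lk.a), ay = m->comy(lk.a);
    double bx = m->comx(lk.b), by = m->comy(lk.b);
    double lo = std::sqrt(sq(ax - bx) + sq(ay - by));
    dE -= lk.lambda * sq(lo - lk.L);
    if (ha && cur_dies) continue;  // link retires with the vanishing cell
    double nax = ax, nay = ay, nbx = bx, nby = by;
    if (lk.a == cur) { nax = cxn; nay = cyn; }
    if (lk.b == cur) { nbx = cxn; nby = cyn; }
    if (lk.a == src) { nax = sxn; nay = syn; }
    if (lk.b == src) { nbx = sxn; nby = syn; }
    double ln = std::sqrt(sq(nax - nbx) + sq(nay - nby));
    dE += lk.lambda * sq(ln - lk.L);
  }
  return dE;
}

static void drop_links_of(CPM* m, int s) {
  m->links.erase(std::remove_if(m->links.begin(), m->links.end(),
                                [s](const Link& lk) { return lk.a == s || lk.b == s; }),
                 m->links.end());
}

static void apply_copy_raw(CPM* m, int x, int y, int src) {
  int cur = m->at(x, y);
  if (cur == src) return;
  for (int k = 0; k < 4; ++k) {
    int nx = x + DX4[k], ny = y + DY4[k];
    int u = (nx < 0 || ny < 0 || nx >= m->W || ny >= m->H) ? 0 : m->at(nx, ny);
    if (cur > 0) m->S[cur] -= (u != cur);
    if (src > 0) m->S[src] += (u != src);
    if (u > 0) m->S[u] += (double)(u != src) - (double)(u != cur);
  }
  if (cur > 0) { m->V[cur] -= 1; m->sumx[cur] -= x; m->sumy[cur] -= y; }
  if (src > 0) { m->V[src] += 1; m->sumx[src] += x; m->sumy[src] += y; }
  m->set(x, y, src);
  if (cur > 0 && m->V[cur] == 0) {
    m->status[cur] = S_ANNIHILATED;  // retired; never returns to the lattice
    m->S[cur] = 0;
    drop_links_of(m, cur);
  }
}

// [[Rcpp::export]]
double cpm_delta_energy(SEXP ptr, int x, int y, int src) {
  XPtr<CPM> m(ptr);
  if (x < 1 || y < 1 || x > m->W || y > m->H) stop("pixel outside lattice");
  if (src < 0 || src >= (int)m->status.size() ||
      (src > 0 && m->status[src] != S_ACTIVE))
    stop("unregistered source index");
  return delta_energy_raw(m, x - 1, y - 1, src);
}

// [[Rcpp::export]]
void cpm_apply_copy(SEXP ptr, int x, int y, int src) {
  XPtr<CPM> m(ptr);
  if (x < 1 || y < 1 || x > m->W || y > m->H) stop("pixel outside lattice");
  apply_copy_raw(m, x - 1, y - 1, src);
}

// ------------------------------------------------------------- Metropolis

static inline bool metro_accept(double dH, double Tm) {
  if (dH <= 0) return true;
  if (Tm <= 0) return false;
  return unif_rand() < std::exp(-dH / Tm);
}

// one pixel-copy attempt; returns 1 if the lattice changed
static int attempt_raw(CPM* m) {
  // the one-pixel frame is immutable medium: targets drawn from the interior
  int x = 1 + (int)(unif_rand() * (m->W - 2));
  int y = 1 + (int)(unif_rand() * (m->H - 2));
  if (x > m->W - 2) x = m->W - 2;
  if (y > m->H - 2) y = m->H - 2;
  int k = (int)(unif_rand() * 8); if (k > 7) k = 7;
  int src = m->at(x + DX8[k], y + DY8[k]);
  int cur = m->at(x, y);
  if (src == cur) return 0;
  double dH = delta_energy_raw(m, x, y, src);
  if (!metro_accept(dH, m->Tm)) return 0;
  apply_copy_raw(m, x, y, src);
  return 1;
}

// [[Rcpp::export]]
int cpm_attempt(SEXP ptr) {
  XPtr<CPM> m(ptr);
  return attempt_raw(m);
}

// empirical acceptance sampler for the bare Metropolis rule
// [[Rcpp::export]]
int cpm_accept_sample(double dH, double Tm, int n) {
  int acc = 0;
  for (int i = 0; i < n; ++i) acc += metro_accept(dH, Tm);
  return acc;
}

// n Monte Carlo steps of bare dynamics (one attempt per lattice pixel each)
// [[Rcpp::export]]
void cpm_sweep(SEXP ptr, int n) {
  XPtr<CPM> m(ptr);
  R_xlen_t per = (R_xlen_t)m->W * m->H;
  for (int i = 0; i < n; ++i) {
    for (R_xlen_t a = 0; a < per; ++a) attempt_raw(m);
    if (i % 8 == 7) Rcpp::checkUserInterrupt();
  }
}

// ------------------------------------------------------------------ links

// Maintain spring links. Existing links persist (mechanical junctions are
// not remade every step) and are dropped only when an endpoint dies, turns
// necrotic, or the separation exceeds the capture range. Cells holding
// fewer than two links then bind their nearest unlinked epithelial
// neighbours within range, closest pairs first, provided the pair's
// contractile target length lies below the current separation. Ties break
// on distance then agent index, so maintenance is deterministic.
static void maintain_links_raw(CPM* m) {
  double maxR = m->linkRange;
  m->links.erase(std::remove_if(m->links.begin(), m->links.end(),
      [m, maxR](const Link& lk) {
        if (!m->is_cell(lk.a) || !m->is_cell(lk.b)) return true;
        if ((m->type[lk.a] != T_LEP && m->type[lk.a] != T_MEP) ||
            (m->type[lk.b] != T_LEP && m->type[lk.b] != T_MEP)) return true;
        double d = std::sqrt(sq(m->comx(lk.a) - m->comx(lk.b)) +
                             sq(m->comy(lk.a) - m->comy(lk.b)));
        return d > maxR;
      }), m->links.end());
  int n = m->status.size();
  std::vector<int> deg(n, 0);
  std::vector<uint64_t> have;
  for (const Link& lk : m->links) {
    ++deg[lk.a]; ++deg[lk.b];
    int a = std::min(lk.a, lk.b), b = std::max(lk.a, lk.b);
    have.push_back((uint64_t)a * (uint64_t)n + b);
  }
  std::sort(have.begin(), have.end());
  std::vector<int> cells;
  for (int s = 1; s < n; ++s)
    if (m->status[s] == S_ACTIVE && (m->type[s] == T_LEP || m->type[s] == T_MEP))
      cells.push_back(s);
  struct Cand { double d; int a, b; };
  std::vector<Cand> cands;
  for (size_t i = 0; i < cells.size(); ++i) {
    int a = cells[i];
    if (deg[a] >= 2) continue;
    for (size_t j = i + 1; j < cells.size(); ++j) {
      int b = cells[j];
      if (deg[b] >= 2) continue;
      double d2 = sq(m->comx(a) - m->comx(b)) + sq(m->comy(a) - m->comy(b));
      if (d2 > maxR * maxR) continue;
      double d = std::sqrt(d2);
      double L = m->fppL[m->type[a]][m->type[b]];
      if (d <= L) continue;  // target must lie below the resting length
      uint64_t key = (uint64_t)std::min(a, b) * (uint64_t)n + std::max(a, b);
      if (std::binary_search(have.begin(), have.end(), key)) continue;
      cands.push_back({d, std::min(a, b), std::max(a, b)});
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& p, const Cand& q) {
    if (p.d != q.d) return p.d < q.d;
    if (p.a != q.a) return p.a < q.a;
    return p.b < q.b;
  });
  for (const Cand& c : cands) {
    if (deg[c.a] >= 2 || deg[c.b] >= 2) continue;
    int ta = m->type[c.a], tb = m->type[c.b];
    m->links.push_back({c.a, c.b, m->fppLam[ta][tb], m->fppL[ta][tb]});
    ++deg[c.a]; ++deg[c.b];
  }
}
static void rebuild_links_raw(CPM* m) { maintain_links_raw(m); }

// [[Rcpp::export]]
void cpm_rebuild_links(SEXP ptr) {
  XPtr<CPM> m(ptr);
  rebuild_links_raw(m);
}

// [[Rcpp::export]]
DataFrame cpm_links(SEXP ptr) {
  XPtr<CPM> m(ptr);
  int n = m->links.size();
  IntegerVector a(n), b(n);
  NumericVector lam(n), L(n), len(n);
  for (int i = 0; i < n; ++i) {
    const Link& lk = m->links[i];
    a[i] = lk.a; b[i] = lk.b; lam[i] = lk.lambda; L[i] = lk.L;
    len[i] = std::sqrt(sq(m->comx(lk.a) - m->comx(lk.b)) + sq(m->comy(lk.a) - m->comy(lk.b)));
  }
  return DataFrame::create(_["a"] = a, _["b"] = b, _["lambda"] = lam,
                           _["L"] = L, _["length"] = len);
}

// [[Rcpp::export]]
void cpm_set_links(SEXP ptr, IntegerVector a, IntegerVector b,
                   NumericVector lambda, NumericVector L) {
  XPtr<CPM> m(ptr);
  m->links.clear();
  for (int i = 0; i < a.size(); ++i) {
    if (!m->is_cell(a[i]) || !m->is_cell(b[i])) stop("link endpoint is not a live cell");
    m->links.push_back({a[i], b[i], lambda[i], L[i]});
  }
}

// ----------------------------------------------------------- death rules

// crowding counts: for each live LEP, number of other live LEP whose
// center of mass lies within `radius` (inclusive); grid-binned. Medium,
// necrotic debris and the myoepithelial sheath never count: the rule
// models crowding pressure within the luminal compartment, and a normal
// contracted monolayer must sit below the overcrowding threshold.
static void crowding_counts_raw(const CPM* m, double radius,
                                std::vector<int>& who, std::vector<int>& cnt) {
  who.clear(); cnt.clear();
  int n = m->status.size();
  std::vector<int> cells;
  for (int s = 1; s < n; ++s)
    if (m->status[s] == S_ACTIVE && m->type[s] == T_LEP)
      cells.push_back(s);
  if (cells.empty()) return;
  double cs = radius;
  int gw = (int)(m->W / cs) + 2, gh = (int)(m->H / cs) + 2;
  std::vector<std::vector<int>> grid(gw * gh);
  std::vector<int> gx(n), gy(n);
  for (int s : cells) {
    int ix = (int)(m->comx(s) / cs) + 1, iy = (int)(m->comy(s) / cs) + 1;
    ix = std::min(std::max(ix, 0), gw - 1);
    iy = std::min(std::max(iy, 0), gh - 1);
    gx[s] = ix; gy[s] = iy;
    grid[ix + iy * gw].push_back(s);
  }
  double r2 = radius * radius;
  for (int s : cells) {
    int c = 0;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ix = gx[s] + dx, iy = gy[s] + dy;
        if (ix < 0 || iy < 0 || ix >= gw || iy >= gh) continue;
        for (int u : grid[ix + iy * gw]) {
          if (u == s) continue;
          if (sq(m->comx(u) - m->comx(s)) + sq(m->comy(u) - m->comy(s)) <= r2) ++c;
        }
      }
    who.push_back(s); cnt.push_back(c);
  }
}

// [[Rcpp::export]]
DataFrame cpm_crowding_counts(SEXP ptr, double radius) {
  XPtr<CPM> m(ptr);
  std::vector<int> who, cnt;
  crowding_counts_raw(m, radius, who, cnt);
  return DataFrame::create(_["sigma"] = wrap(who), _["n_within"] = wrap(cnt));
}

static void remove_agent_raw(CPM* m, int s) {
  for (size_t i = 0; i < m->sigma.size(); ++i)
    if (m->sigma[i] == s) m->sigma[i] = 0;
  m->status[s] = S_REMOVED;
  m->V[s] = 0; m->S[s] = 0; m->sumx[s] = 0; m->sumy[s] = 0;
  drop_links_of(m, s);
}

// [[Rcpp::export]]
void cpm_remove_agent(SEXP ptr, int s) {
  XPtr<CPM> m(ptr);
  if (s <= 0 || s >= (int)m->status.size() || m->status[s] != S_ACTIVE)
    stop("not a live agent");
  remove_agent_raw(m, s);
}

static void make_necrotic_raw(CPM* m, int s) {
  m->type[s] = T_NECROTIC;
  drop_links_of(m, s);
}

// [[Rcpp::export]]
void cpm_set_type(SEXP ptr, int s, int type) {
  XPtr<CPM> m(ptr);
  if (s <= 0 || s >= (int)m->status.size() || m->status[s] != S_ACTIVE)
    stop("not a live agent");
  if (type == T_NECROTIC) make_necrotic_raw(m, s);
  else m->type[s] = type;
}

// exact distance from each live LEP's center of mass to the nearest MEP
// pixel (brute force over MEP pixels; used by tests and the necrosis rule)
// [[Rcpp::export]]
DataFrame cpm_mep_distance(SEXP ptr) {
  XPtr<CPM> m(ptr);
  std::vector<std::pair<int,int>> mep;
  for (int y = 0; y < m->H; ++y)
    for (int x = 0; x < m->W; ++x) {
      int s = m->at(x, y);
      if (s > 0 && m->type[s] == T_MEP) mep.push_back({x, y});
    }
  std::vector<int> who; std::vector<double> dist;
  for (size_t s = 1; s < m->status.size(); ++s) {
    if (m->status[s] != S_ACTIVE || m->type[s] != T_LEP) continue;
    double cx = m->comx(s), cy = m->comy(s), best = R_PosInf;
    for (auto& p : mep) best = std::min(best, sq(p.first - cx) + sq(p.second - cy));
    who.push_back(s); dist.push_back(std::sqrt(best));
  }
  return DataFrame::create(_["sigma"] = wrap(who), _["dist_mep"] = wrap(dist));
}

// necrosis candidates: live LEP at >= dist from the nearest MEP pixel.
// Cheap screen on MEP center-of-mass distances; exact pixel search only for
// agents the screen cannot clear.
static void necrosis_candidates_raw(CPM* m, double dist, std::vector<int>& out) {
  out.clear();
  int n = m->status.size();
  std::vector<int> meps, leps;
  for (int s = 1; s < n; ++s) {
    if (m->status[s] != S_ACTIVE) continue;
    if (m->type[s] == T_MEP) meps.push_back(s);
    else if (m->type[s] == T_LEP) leps.push_back(s);
  }
  if (meps.empty() || leps.empty()) return;
  std::vector<int> cand;
  for (int s : leps) {
    double cx = m->comx(s), cy = m->comy(s), best = R_PosInf;
    for (int u : meps) best = std::min(best, sq(m->comx(u) - cx) + sq(m->comy(u) - cy));
    // a compact MEP cell has a pixel within a few px of its center of mass
    if (best > sq(std::max(dist - 15.0, 0.0))) cand.push_back(s);
  }
  if (cand.empty()) return;
  std::vector<std::pair<int,int>> mep_px;
  for (int y = 0; y < m->H; ++y)
    for (int x = 0; x < m->W; ++x) {
      int s = m->at(x, y);
      if (s > 0 && m->type[s] == T_MEP) mep_px.push_back({x, y});
    }
  double d2 = dist * dist;
  for (int s : cand) {
    double cx = m->comx(s), cy = m->comy(s);
    bool close = false;
    for (auto& p : mep_px)
      if (sq(p.first - cx) + sq(p.second - cy) < d2) { close = true; break; }
    if (!close) out.push_back(s);
  }
}

// [[Rcpp::export]]
IntegerVector cpm_necrosis_candidates(SEXP ptr, double dist) {
  XPtr<CPM> m(ptr);
  std::vector<int> out;
  necrosis_candidates_raw(m, dist, out);
  return wrap(out);
}

// ------------------------------------------------------------- run block

// n MCS of Metropolis dynamics with the per-MCS death hooks (apoptosis then
// necrosis) and a link rebuild after any topology-changing event. Mitosis
// is orchestrated from R between blocks. Returns the event log.
// [[Rcpp::export]]
DataFrame cpm_run_block(SEXP ptr, int n, double apop_prob, double apop_radius,
                        int apop_threshold, double necro_dist,
                        bool do_apoptosis, bool do_necrosis, int mcs_offset) {
  XPtr<CPM> m(ptr);
  R_xlen_t per = (R_xlen_t)m->W * m->H;
  std::vector<int> ev_mcs, ev_code, ev_sigma;
  std::vector<double> ev_x, ev_y;
  std::vector<int> who, cnt, necro;
  for (int i = 0; i < n; ++i) {
    for (R_xlen_t a = 0; a < per; ++a) attempt_raw(m);
    bool changed = false;
    if (do_apoptosis) {
      crowding_counts_raw(m, apop_radius, who, cnt);
      for (size_t k = 0; k < who.size(); ++k) {
        int s = who[k];
        if (cnt[k] < apop_threshold) continue;      // not overcrowded
        if (m->prot[s]) continue;                   // protected progeny
        if (apop_prob > 0 && unif_rand() < apop_prob) {
          ev_mcs.push_back(mcs_offset + i + 1); ev_code.push_back(1);
          ev_sigma.push_back(s); ev_x.push_back(m->comx(s) + 1); ev_y.push_back(m->comy(s) + 1);
          remove_agent_raw(m, s);
          changed = true;
        }
      }
    }
    if (do_necrosis) {
      necrosis_candidates_raw(m, necro_dist, necro);
      for (int s : necro) {
        ev_mcs.push_back(mcs_offset + i + 1); ev_code.push_back(2);
        ev_sigma.push_back(s); ev_x.push_back(m->comx(s) + 1); ev_y.push_back(m->comy(s) + 1);
        make_necrotic_raw(m, s);
        changed = true;
      }
    }
    (void)changed;
    maintain_links_raw(m);
    if (i % 4 == 3) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["mcs"] = wrap(ev_mcs), _["code"] = wrap(ev_code),
                           _["sigma"] = wrap(ev_sigma), _["x"] = wrap(ev_x),
                           _["y"] = wrap(ev_y));
}

// --------------------------------------------------------------- mitosis

// split agent s by a straight cut through its center of mass along
// direction (dx, dy); pixels strictly on the negative side go to a fresh
// daughter index which inherits the parent's type and constraint targets
// [[Rcpp::export]]
int cpm_divide(SEXP ptr, int s, double dx, double dy) {
  XPtr<CPM> m(ptr);
  if (s <= 0 || s >= (int)m->status.size() || m->status[s] != S_ACTIVE)
    stop("not a live agent");
  if (m->V[s] < 2) stop("cell volume below 2; division skipped");
  double cx = m->comx(s), cy = m->comy(s);
  std::vector<std::pair<int,int>> px;
  for (int y = 0; y < m->H; ++y)
    for (int x = 0; x < m->W; ++x)
      if (m->at(x, y) == s) px.push_back({x, y});
  std::vector<double> side(px.size());
  double nrm = std::sqrt(dx * dx + dy * dy);
  if (nrm == 0) stop("zero cut direction");
  for (size_t i = 0; i < px.size(); ++i)
    side[i] = (px[i].first - cx) * (-dy / nrm) + (px[i].second - cy) * (dx / nrm);
  std::vector<int> idx(px.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::vector<char> daughter(px.size(), 0);
  int nneg = 0;
  for (size_t i = 0; i < px.size(); ++i)
    if (side[i] < 0) { daughter[i] = 1; ++nneg; }
  if (nneg == 0 || nneg == (int)px.size()) {
    // degenerate cut (e.g. all pixels on the line): halve by signed offset
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (side[a] != side[b]) return side[a] < side[b];
      if (px[a].first != px[b].first) return px[a].first < px[b].first;
      return px[a].second < px[b].second;
    });
    std::fill(daughter.begin(), daughter.end(), 0);
    for (size_t i = 0; i < px.size() / 2; ++i) daughter[idx[i]] = 1;
  }
  int d = m->status.size();
  m->type.push_back(m->type[s]);
  m->status.push_back(S_ACTIVE);
  m->V.push_back(0); m->S.push_back(0);
  m->Vt.push_back(m->Vt[s]); m->St.push_back(m->St[s]);
  m->lamV.push_back(m->lamV[s]); m->lamS.push_back(m->lamS[s]);
  m->sumx.push_back(0); m->sumy.push_back(0);
  m->prot.push_back(0);
  for (size_t i = 0; i < px.size(); ++i)
    if (daughter[i]) m->set(px[i].first, px[i].second, d);
  // recompute bookkeeping for parent and daughter from their pixels
  for (int a : {s, d}) { m->V[a] = 0; m->S[a] = 0; m->sumx[a] = 0; m->sumy[a] = 0; }
  for (size_t i = 0; i < px.size(); ++i) {
    int a = daughter[i] ? d : s;
    int x = px[i].first, y = px[i].second;
    m->V[a] += 1; m->sumx[a] += x; m->sumy[a] += y;
    for (int k = 0; k < 4; ++k) {
      int nx = x + DX4[k], ny = y + DY4[k];
      int u = (nx < 0 || ny < 0 || nx >= m->W || ny >= m->H) ? 0 : m->at(nx, ny);
      if (u != a) m->S[a] += 1;
    }
  }
  return d;
}

// ------------------------------------------------------------- accessors

// [[Rcpp::export]]
IntegerMatrix cpm_lattice(SEXP ptr) {
  XPtr<CPM> m(ptr);
  IntegerMatrix out(m->W, m->H);
  std::copy(m->sigma.begin(), m->sigma.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
DataFrame cpm_agents(SEXP ptr) {
  XPtr<CPM> m(ptr);
  int n = m->status.size();
  std::vector<int> sig, typ, stat; std::vector<double> V, S, Vt, St, lv, ls, x, y;
  std::vector<int> pr;
  for (int s = 1; s < n; ++s) {
    if (m->status[s] == S_FREE) continue;
    sig.push_back(s); typ.push_back(m->type[s]); stat.push_back(m->status[s]);
    V.push_back(m->V[s]); S.push_back(m->S[s]);
    Vt.push_back(m->Vt[s]); St.push_back(m->St[s]);
    lv.push_back(m->lamV[s]); ls.push_back(m->lamS[s]);
    if (m->V[s] > 0) { x.push_back(m->comx(s) + 1); y.push_back(m->comy(s) + 1); }
    else { x.push_back(NA_REAL); y.push_back(NA_REAL); }
    pr.push_back(m->prot[s]);
  }
  return DataFrame::create(_["sigma"] = wrap(sig), _["type"] = wrap(typ),
                           _["status"] = wrap(stat), _["V"] = wrap(V),
                           _["S"] = wrap(S), _["Vt"] = wrap(Vt), _["St"] = wrap(St),
                           _["lambda_V"] = wrap(lv), _["lambda_S"] = wrap(ls),
                           _["x"] = wrap(x), _["y"] = wrap(y),
                           _["protected"] = wrap(pr));
}

// [[Rcpp::export]]
NumericMatrix cpm_cell_pixels(SEXP ptr, int s) {
  XPtr<CPM> m(ptr);
  std::vector<double> xs, ys;
  for (int y = 0; y < m->H; ++y)
    for (int x = 0; x < m->W; ++x)
      if (m->at(x, y) == s) { xs.push_back(x + 1); ys.push_back(y + 1); }
  NumericMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  colnames(out) = CharacterVector::create("x", "y");
  return out;
}

// [[Rcpp::export]]
void cpm_set_protected(SEXP ptr, int s, bool flag) {
  XPtr<CPM> m(ptr);
  if (s <= 0 || s >= (int)m->status.size()) stop("no such agent");
  m->prot[s] = flag;
}

// [[Rcpp::export]]
void cpm_set_temperature(SEXP ptr, double Tm) {
  XPtr<CPM> m(ptr);
  m->Tm = Tm;
}

// largest 4-connected component of each live cell, as a fraction of its
// volume (fragmentation diagnostic)
// [[Rcpp::export]]
DataFrame cpm_connectivity(SEXP ptr) {
  XPtr<CPM> m(ptr);
  int n = m->status.size();
  std::vector<double> largest(n, 0);
  std::vector<char> visited(m->sigma.size(), 0);
  std::vector<int> stack;
  for (int y = 0; y < m->H; ++y)
    for (int x = 0; x < m->W; ++x) {
      int s = m->at(x, y);
      size_t i0 = x + (size_t)y * m->W;
      if (s == 0 || visited[i0]) continue;
      int sz = 0;
      stack.clear(); stack.push_back(i0); visited[i0] = 1;
      while (!stack.empty()) {
        int i = stack.back(); stack.pop_back(); ++sz;
        int px = i % m->W, py = i / m->W;
        for (int k = 0; k < 4; ++k) {
          int nx = px + DX4[k], ny = py + DY4[k];
          if (nx < 0 || ny < 0 || nx >= m->W || ny >= m->H) continue;
          int j = nx + ny * m->W;
          if (!visited[j] && m->sigma[j] == s) { visited[j] = 1; stack.push_back(j); }
        }
      }
      largest[s] = std::max(largest[s], (double)sz);
    }
  std::vector<int> sig; std::vector<double> frac;
  for (int s = 1; s < n; ++s)
    if (m->status[s] == S_ACTIVE && m->V[s] > 0) {
      sig.push_back(s); frac.push_back(largest[s] / m->V[s]);
    }
  return DataFrame::create(_["sigma"] = wrap(sig), _["largest_frac"] = wrap(frac));
}

// connected-component labelling of a binary mask (4- or 8-connectivity);
// EBImage::bwlabel is 4-connected only, and the morphology rules need both
// [[Rcpp::export]]
IntegerMatrix cc_label(IntegerMatrix mask, bool eight) {
  int W = mask.nrow(), H = mask.ncol();
  IntegerMatrix lab(W, H);
  int nl = 0;
  std::vector<int> stack;
  const int* dx = eight ? DX8 : DX4;
  const int* dy = eight ? DY8 : DY4;
  int nk = eight ? 8 : 4;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (mask(x, y) == 0 || lab(x, y) != 0) continue;
      ++nl;
      stack.clear(); stack.push_back(x + y * W); lab(x, y) = nl;
      while (!stack.empty()) {
        int i = stack.back(); stack.pop_back();
        int px = i % W, py = i / W;
        for (int k = 0; k < nk; ++k) {
          int nx = px + dx[k], ny = py + dy[k];
          if (nx < 0 || ny < 0 || nx >= W || ny >= H) continue;
          if (mask(nx, ny) != 0 && lab(nx, ny) == 0) {
            lab(nx, ny) = nl;
            stack.push_back(nx + ny * W);
          }
        }
      }
    }
  return lab;
}
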