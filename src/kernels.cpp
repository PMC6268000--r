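#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Residue-wise minimum cross distances between two backbone-site sets.
// A: nA x 3, B: nB x 3 (nm). Returns c(minA_1..minA_nA, minB_1..minB_nB).
// [[Rcpp::export(name = ".rmd_cpp")]]
NumericVector rmd_cpp(NumericMatrix A, NumericMatrix B) {
  int nA = A.nrow(), nB = B.nrow();
  NumericVector out(nA + nB);
  std::vector<double> minB(nB, R_PosInf);
  for (int i = 0; i < nA; ++i) {
    double best = R_PosInf;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nB; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
      if (d2 < minB[j]) minB[j] = d2;
    }
    out[i] = std::sqrt(best);
  }
  for (int j = 0; j < nB; ++j) out[nA + j] = std::sqrt(minB[j]);
  return out;
}

// Shrake-Rupley SASA with a deterministic Fibonacci sphere point set.
// coords: n x 3 (nm); radii: length n (nm); subset: 1-based particle indices
// to evaluate (all particles always occlude). Returns area (nm^2) per subset
// entry.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points, IntegerVector subset) {
  int n = coords.nrow();
  int ns = subset.size();
  // Fibonacci sphere (unit vectors), deterministic for fixed n_points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }
  NumericVector out(ns);
  std::vector<int> nbr;
  for (int s = 0; s < ns; ++s) {
    int i = subset[s] - 1;
    double Ri = radii[i] + probe;
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double Rj = radii[j] + probe;
      double dx = xi - coords(j, 0), dy = yi - coords(j, 1),
             dz = zi - coords(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rr = Ri + Rj;
      if (d2 < rr * rr) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xi + Ri * px[k], qy = yi + Ri * py[k], qz = zi + Ri * pz[k];
      bool free_pt = true;
      for (size_t t = 0; t < nbr.size(); ++t) {
        int j = nbr[t];
        double Rj = radii[j] + probe;
        double dx = qx - coords(j, 0), dy = qy - coords(j, 1),
               dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    out[s] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)n_points;
  }
  return out;
}

// Exact balanced transportation problem (discrete optimal transport).
// a: supplies (m), b: demands (n), cost: m x n ground distances.
// Transportation simplex (u-v method) on a spanning-tree basis with an
// epsilon perturbation against degenerate cycling; the optimal basis is
// re-solved with the unperturbed marginals before costing, so the returned
// value is exact up to floating point.
// [[Rcpp::export(name = ".emd_cpp")]]
double emd_cpp(NumericVector a, NumericVector b, NumericMatrix cost) {
  int m = a.size(), n = b.size(), N = m + n;
  std::vector<double> sa(a.begin(), a.end()), sb(b.begin(), b.end());
  double total = 0.0, cmax = 0.0;
  for (int i = 0; i < m; ++i) total += sa[i];
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) if (cost(i, j) > cmax) cmax = cost(i, j);
  double delta = (total > 0 ? total : 1.0) * 1e-13 / (m + 1);
  double extra = 0.0;
  for (int i = 0; i < m; ++i) { sa[i] += delta * (i + 1); extra += delta * (i + 1); }
  sb[n - 1] += extra;

  struct Edge { int i, j; double flow; bool alive; };
  std::vector<Edge> edges;
  edges.reserve(2 * N);
  std::vector<std::vector<int> > adj(N);

  { // northwest-corner initial basis: exactly m+n-1 arcs
    std::vector<double> ra = sa, rb = sb;
    int i = 0, j = 0;
    while (true) {
      double f = std::min(ra[i], rb[j]);
      Edge e; e.i = i; e.j = j; e.flow = f; e.alive = true;
      int id = (int)edges.size();
      edges.push_back(e);
      adj[i].push_back(id);
      adj[m + j].push_back(id);
      ra[i] -= f; rb[j] -= f;
      if (i == m - 1 && j == n - 1) break;
      if (i < m - 1 && (j == n - 1 || ra[i] < rb[j])) ++i; else ++j;
    }
  }

  const double EPS = 1e-12 * (1.0 + cmax);
  long maxit = 400L * N + 20000L;
  std::vector<double> pot(N);
  std::vector<char> vis(N);
  std::vector<int> par(N), parEdge(N);
  bool converged = false;

  for (long it = 0; it < maxit; ++it) {
    // node potentials from the basis tree
    std::fill(vis.begin(), vis.end(), 0);
    pot[0] = 0.0; vis[0] = 1;
    std::deque<int> q; q.push_back(0);
    while (!q.empty()) {
      int x = q.front(); q.pop_front();
      for (size_t t = 0; t < adj[x].size(); ++t) {
        int id = adj[x][t];
        const Edge &e = edges[id];
        int y = (x == e.i) ? (m + e.j) : e.i;
        if (!vis[y]) { vis[y] = 1; pot[y] = cost(e.i, e.j) - pot[x]; q.push_back(y); }
      }
    }
    // entering arc: most negative reduced cost
    double best = -EPS; int bi = -1, bj = -1;
    for (int i = 0; i < m; ++i) {
      double ui = pot[i];
      for (int j = 0; j < n; ++j) {
        double rc = cost(i, j) - ui - pot[m + j];
        if (rc < best) { best = rc; bi = i; bj = j; }
      }
    }
    if (bi < 0) { converged = true; break; }
    // tree path from sink (m+bj) back to source bi
    std::fill(vis.begin(), vis.end(), 0);
    vis[bi] = 1; par[bi] = -1;
    q.clear(); q.push_back(bi);
    while (!q.empty()) {
      int x = q.front(); q.pop_front();
      if (x == m + bj) break;
      for (size_t t = 0; t < adj[x].size(); ++t) {
        int id = adj[x][t];
        const Edge &e = edges[id];
        int y = (x == e.i) ? (m + e.j) : e.i;
        if (!vis[y]) { vis[y] = 1; par[y] = x; parEdge[y] = id; q.push_back(y); }
      }
    }
    // cycle: entering arc (+), then alternate along the path
    std::vector<int> path; // edge ids from m+bj back to bi
    for (int x = m + bj; par[x] != -1; x = par[x]) path.push_back(parEdge[x]);
    double theta = R_PosInf; int leave = -1;
    for (size_t t = 0; t < path.size(); ++t) {
      if (t % 2 == 0) { // minus arc
        double f = edges[path[t]].flow;
        if (f < theta) { theta = f; leave = path[t]; }
      }
    }
    for (size_t t = 0; t < path.size(); ++t) {
      if (t % 2 == 0) edges[path[t]].flow -= theta;
      else edges[path[t]].flow += theta;
    }
    // swap arcs in the basis
    Edge en; en.i = bi; en.j = bj; en.flow = theta; en.alive = true;
    int id = (int)edges.size();
    edges.push_back(en);
    adj[bi].push_back(id);
    adj[m + bj].push_back(id);
    edges[leave].alive = false;
    int li = edges[leave].i, lj = m + edges[leave].j;
    adj[li].erase(std::find(adj[li].begin(), adj[li].end(), leave));
    adj[lj].erase(std::find(adj[lj].begin(), adj[lj].end(), leave));
  }
  if (!converged)
    Rf_warning("transportation simplex hit the pivot cap; result may be approximate");

  // re-solve basis flows with unperturbed marginals (leaf elimination)
  std::vector<double> bal(N);
  for (int i = 0; i < m; ++i) bal[i] = a[i];
  for (int j = 0; j < n; ++j) bal[m + j] = -b[j];
  std::vector<int> deg(N);
  for (int x = 0; x < N; ++x) deg[x] = (int)adj[x].size();
  std::vector<char> done(N, 0);
  std::vector<char> used(edges.size(), 0);
  std::deque<int> leaves;
  for (int x = 0; x < N; ++x) if (deg[x] == 1) leaves.push_back(x);
  double value = 0.0;
  while (!leaves.empty()) {
    int x = leaves.front(); leaves.pop_front();
    if (done[x]) continue;
    int eid = -1;
    for (size_t t = 0; t < adj[x].size(); ++t) {
      int id = adj[x][t];
      if (edges[id].alive && !used[id]) { eid = id; break; }
    }
    if (eid < 0) { done[x] = 1; continue; }
    const Edge &e = edges[eid];
    double f = (x < m) ? bal[x] : -bal[x];
    int y = (x == e.i) ? (m + e.j) : e.i;
    if (x < m) bal[m + e.j] += f; else bal[e.i] -= f;
    value += f * cost(e.i, e.j);
    used[eid] = 1;
    done[x] = 1;
    if (--deg[y] == 1 && !done[y]) leaves.push_back(y);
  }
  return value;
}
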