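#include <Rcpp.h>
#include <vector>
#include <queue>
#include <set>
#include <cstring>
using namespace Rcpp;

// --- topology helpers on the 3x3x3 neighbourhood ---------------------------

// cells indexed 0..26 as (dx+1) + 3*(dy+1) + 9*(dz+1); centre = 13

static inline bool adj26(int a, int b) {
  int ax = a % 3, ay = (a / 3) % 3, az = a / 9;
  int bx = b % 3, by = (b / 3) % 3, bz = b / 9;
  int dx = std::abs(ax - bx), dy = std::abs(ay - by), dz = std::abs(az - bz);
  return (dx <= 1 && dy <= 1 && dz <= 1) && (dx + dy + dz > 0);
}
static inline bool adj6(int a, int b) {
  int ax = a % 3, ay = (a / 3) % 3, az = a / 9;
  int bx = b % 3, by = (b / 3) % 3, bz = b / 9;
  return std::abs(ax - bx) + std::abs(ay - by) + std::abs(az - bz) == 1;
}

// Simple-point test (Malandain & Bertrand characterisation): a border object
// voxel is simple iff the object in its 26-neighbourhood has exactly one
// 26-component, and the background restricted to the 18-neighbourhood has
// exactly one 6-component that is 6-adjacent to the centre.
static bool is_simple(const bool nb[27]) {
  // object components (26-connectivity) among the 26 neighbours
  bool seen[27] = {false};
  int ncomp_obj = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++ncomp_obj;
    if (ncomp_obj > 1) return false;
    std::queue<int> q; q.push(i); seen[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      for (int j = 0; j < 27; ++j)
        if (j != 13 && nb[j] && !seen[j] && adj26(c, j)) { seen[j] = true; q.push(j); }
    }
  }
  if (ncomp_obj != 1) return false;

  // background 6-components in the 18-neighbourhood, 6-adjacent to centre
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int ax = i % 3 - 1, ay = (i / 3) % 3 - 1, az = i / 9 - 1;
    in18[i] = (i != 13) && (std::abs(ax) + std::abs(ay) + std::abs(az) <= 2);
  }
  bool seenb[27] = {false};
  int ncomp_bg = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || seenb[i]) continue;
    // flood this background component within N18
    std::vector<int> comp;
    std::queue<int> q; q.push(i); seenb[i] = true;
    bool touches_centre = false;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      if (adj6(c, 13)) touches_centre = true;
      for (int j = 0; j < 27; ++j)
        if (in18[j] && !nb[j] && !seenb[j] && adj6(c, j)) { seenb[j] = true; q.push(j); }
    }
    if (touches_centre) {
      ++ncomp_bg;
      if (ncomp_bg > 1) return false;
    }
  }
  return ncomp_bg == 1;
}

// --- thinning ---------------------------------------------------------------

// Topology-preserving sequential 3D thinning to a unit-width curve skeleton.
// Six directional sub-iterations per pass; curve endpoints (<= 1 object
// neighbour) are preserved.
// [[Rcpp::export]]
LogicalVector cc_thin3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] ? 1 : 0;

  auto at = [&](int x, int y, int z) -> char {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return m[x + nx * (y + (R_xlen_t)ny * z)];
  };
  auto nbhd = [&](int x, int y, int z, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[(dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)] = at(x + dx, y + dy, z + dz);
  };
  auto n_neighbours = [&](const bool nb[27]) {
    int c = 0;
    for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
    return c;
  };

  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            if (!at(x, y, z)) continue;
            if (at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
            cand.push_back(x + nx * (y + ny * z));
          }
      for (size_t i = 0; i < cand.size(); ++i) {
        int idx = cand[i];
        if (!m[idx]) continue;
        int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
        bool nb[27];
        nbhd(x, y, z, nb);
        if (n_neighbours(nb) <= 1) continue;  // curve endpoint, keep
        if (!is_simple(nb)) continue;
        m[idx] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = m[i] != 0;
  return out;
}

// --- skeleton -> graph ------------------------------------------------------

// Converts a unit-width voxel skeleton into a spatial graph. Node voxels are
// skeleton voxels with 26-degree != 2; 26-adjacent node voxels are merged
// into junction clusters. Edges are traced through degree-2 chains. Pure
// cycles with no node voxel get a single anchor node. Coordinates are in µm
// (voxel centres at (index - 1) * spacing for 1-based R indices).
// [[Rcpp::export]]
List cc_skel_graph(LogicalVector skel, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = skel.size();

  auto at = [&](int x, int y, int z) -> bool {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return false;
    return skel[x + nx * (y + (R_xlen_t)ny * z)];
  };
  auto neighbours = [&](int idx, std::vector<int>& out) {
    out.clear();
    int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          if (at(x + dx, y + dy, z + dz))
            out.push_back((x + dx) + nx * ((y + dy) + ny * (z + dz)));
        }
  };

  std::vector<int> deg(n, 0);
  std::vector<int> nbuf;
  std::vector<int> voxels;
  for (R_xlen_t i = 0; i < n; ++i)
    if (skel[i]) {
      neighbours((int)i, nbuf);
      deg[i] = (int)nbuf.size();
      voxels.push_back((int)i);
    }

  // cluster node voxels (deg != 2)
  std::vector<int> cluster(n, 0);
  int nclust = 0;
  for (int v : voxels) {
    if (deg[v] == 2 || cluster[v]) continue;
    ++nclust;
    std::queue<int> q; q.push(v); cluster[v] = nclust;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      neighbours(c, nbuf);
      for (int w : nbuf)
        if (deg[w] != 2 && !cluster[w]) { cluster[w] = nclust; q.push(w); }
    }
  }

  // cluster centroids (µm)
  std::vector<double> cx(nclust, 0), cy(nclust, 0), cz(nclust, 0);
  std::vector<int> cn(nclust, 0);
  for (int v : voxels) {
    if (!cluster[v]) continue;
    int k = cluster[v] - 1;
    cx[k] += (v % nx) * spacing[0];
    cy[k] += ((v / nx) % ny) * spacing[1];
    cz[k] += (v / (nx * ny)) * spacing[2];
    cn[k] += 1;
  }

  std::vector<char> visited(n, 0);          // chain voxels consumed by an edge
  std::vector<std::vector<int>> paths;       // voxel-index paths
  std::vector<std::pair<int,int>> ends;      // cluster ids (1-based)
  std::set<std::pair<int,int>> direct_seen;  // dedup direct cluster contacts

  for (int v : voxels) {
    if (!cluster[v]) continue;
    neighbours(v, nbuf);
    std::vector<int> nbv = nbuf;
    for (int w : nbv) {
      if (cluster[w]) {
        if (cluster[w] != cluster[v]) {
          int a = std::min(cluster[v], cluster[w]), b = std::max(cluster[v], cluster[w]);
          if (direct_seen.insert({a, b}).second) {
            paths.push_back({v, w});
            ends.push_back({cluster[v], cluster[w]});
          }
        }
        continue;
      }
      if (visited[w]) continue;
      // walk the degree-2 chain
      std::vector<int> path;
      path.push_back(v);
      int prev = v, cur = w;
      visited[cur] = 1;
      path.push_back(cur);
      while (true) {
        neighbours(cur, nbuf);
        int nxt = -1;
        for (int u : nbuf) if (u != prev) { nxt = u; break; }
        if (nxt < 0) break;  // dangling chain end (shouldn't happen)
        path.push_back(nxt);
        if (cluster[nxt]) break;
        if (visited[nxt]) break;  // safety
        visited[nxt] = 1;
        prev = cur; cur = nxt;
      }
      int endc = cluster[path.back()];
      paths.push_back(path);
      ends.push_back({cluster[v], endc});
    }
  }

  // pure cycles: remaining unvisited degree-2 voxels with no cluster
  for (int v : voxels) {
    if (deg[v] != 2 || visited[v] || cluster[v]) continue;
    ++nclust;
    cluster[v] = nclust;
    cx.push_back((v % nx) * spacing[0]);
    cy.push_back(((v / nx) % ny) * spacing[1]);
    cz.push_back((v / (nx * ny)) * spacing[2]);
    cn.push_back(1);
    std::vector<int> path;
    path.push_back(v);
    neighbours(v, nbuf);
    int prev = v, cur = nbuf[0];
    while (cur != v && !visited[cur]) {
      visited[cur] = 1;
      path.push_back(cur);
      neighbours(cur, nbuf);
      int nxt = -1;
      for (int u : nbuf) if (u != prev) { nxt = u; break; }
      if (nxt < 0) break;
      prev = cur; cur = nxt;
    }
    path.push_back(v);
    paths.push_back(path);
    ends.push_back({nclust, nclust});
  }

  // assemble outputs
  NumericMatrix nodes(nclust, 3);
  for (int k = 0; k < nclust; ++k) {
    nodes(k, 0) = cx[k] / cn[k];
    nodes(k, 1) = cy[k] / cn[k];
    nodes(k, 2) = cz[k] / cn[k];
  }
  List edge_paths(paths.size());
  IntegerMatrix edge_ends(paths.size(), 2);
  for (size_t e = 0; e < paths.size(); ++e) {
    NumericMatrix pm(paths[e].size(), 3);
    for (size_t j = 0; j < paths[e].size(); ++j) {
      int idx = paths[e][j];
      pm(j, 0) = (idx % nx) * spacing[0];
      pm(j, 1) = ((idx / nx) % ny) * spacing[1];
      pm(j, 2) = (idx / (nx * ny)) * spacing[2];
    }
    edge_paths[e] = pm;
    edge_ends(e, 0) = ends[e].first;
    edge_ends(e, 1) = ends[e].second;
  }
  return List::create(_["nodes"] = nodes,
                      _["edge_paths"] = edge_paths,
                      _["edge_ends"] = edge_ends);
}
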