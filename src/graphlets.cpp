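#include <Rcpp.h>
#include <vector>
#include <set>
using namespace Rcpp;

// Orbit counting for 2-4-node graphlets (15 automorphism orbits, standard
// numbering: 0 edge; 1/2 path ends/middle; 3 triangle; 4/5 P4 ends/middles;
// 6/7 claw leaves/center; 8 C4; 9/10/11 paw pendant/side/hub; 12/13 diamond
// deg-2/deg-3; 14 K4). Connected induced subgraphs are enumerated exactly
// once with the ESU scheme and classified by induced degree sequence.

static std::vector<std::vector<int>> adj;          // sorted adjacency lists
static std::vector<std::vector<bool>> amat;        // adjacency matrix

static inline bool connected(int a, int b) { return amat[a][b]; }

static void classify3(int a, int b, int c, IntegerMatrix& orb) {
  int eab = connected(a, b), eac = connected(a, c), ebc = connected(b, c);
  int m = eab + eac + ebc;
  int v[3] = {a, b, c};
  int deg[3] = {eab + eac, eab + ebc, eac + ebc};
  if (m == 3) {
    for (int k = 0; k < 3; k++) orb(v[k], 3)++;
  } else { // m == 2: induced path
    for (int k = 0; k < 3; k++) orb(v[k], deg[k] == 2 ? 2 : 1)++;
  }
}

static void classify4(int a, int b, int c, int d, IntegerMatrix& orb) {
  int v[4] = {a, b, c, d};
  int deg[4] = {0, 0, 0, 0};
  int m = 0;
  for (int i = 0; i < 4; i++)
    for (int j = i + 1; j < 4; j++)
      if (connected(v[i], v[j])) { deg[i]++; deg[j]++; m++; }
  switch (m) {
  case 3: {
    bool star = false;
    for (int k = 0; k < 4; k++) if (deg[k] == 3) star = true;
    if (star) {
      for (int k = 0; k < 4; k++) orb(v[k], deg[k] == 3 ? 7 : 6)++;
    } else { // P4
      for (int k = 0; k < 4; k++) orb(v[k], deg[k] == 2 ? 5 : 4)++;
    }
    break;
  }
  case 4: {
    bool cyc = true;
    for (int k = 0; k < 4; k++) if (deg[k] != 2) cyc = false;
    if (cyc) {
      for (int k = 0; k < 4; k++) orb(v[k], 8)++;
    } else { // paw
      for (int k = 0; k < 4; k++)
        orb(v[k], deg[k] == 1 ? 9 : (deg[k] == 3 ? 11 : 10))++;
    }
    break;
  }
  case 5:
    for (int k = 0; k < 4; k++) orb(v[k], deg[k] == 3 ? 13 : 12)++;
    break;
  case 6:
    for (int k = 0; k < 4; k++) orb(v[k], 14)++;
    break;
  }
}

// ESU extension step
static void extend(int v, std::vector<int>& sub, std::vector<int>& ext,
                   std::vector<char>& in_nbhd, IntegerMatrix& orb) {
  int size = sub.size();
  if (size == 4) return;
  // iterate over a private copy; remove w from ext as we go
  std::vector<int> ext_local = ext;
  while (!ext_local.empty()) {
    int w = ext_local.back();
    ext_local.pop_back();
    sub.push_back(w);
    if (sub.size() == 3) classify3(sub[0], sub[1], sub[2], orb);
    if (sub.size() == 4) classify4(sub[0], sub[1], sub[2], sub[3], orb);
    if (sub.size() < 4) {
      // extension set: ext_local plus exclusive neighbours of w (> v, not in
      // the neighbourhood of the current subgraph)
      std::vector<int> ext_next = ext_local;
      std::vector<int> added;
      for (int u : adj[w]) {
        if (u > v && !in_nbhd[u]) {
          ext_next.push_back(u);
          in_nbhd[u] = 1;
          added.push_back(u);
        }
      }
      extend(v, sub, ext_next, in_nbhd, orb);
      for (int u : added) in_nbhd[u] = 0;
    }
    sub.pop_back();
  }
}

// [[Rcpp::export]]
IntegerMatrix count_graphlet_orbits(int n, IntegerMatrix edges) {
  adj.assign(n, std::vector<int>());
  amat.assign(n, std::vector<bool>(n, false));
  for (int e = 0; e < edges.nrow(); e++) {
    int a = edges(e, 0), b = edges(e, 1);
    if (a == b) continue;
    if (!amat[a][b]) {
      amat[a][b] = amat[b][a] = true;
      adj[a].push_back(b);
      adj[b].push_back(a);
    }
  }
  IntegerMatrix orb(n, 15);
  for (int v = 0; v < n; v++) {
    orb(v, 0) = adj[v].size();
    std::vector<int> sub{v};
    std::vector<int> ext;
    std::vector<char> in_nbhd(n, 0);
    in_nbhd[v] = 1;
    for (int u : adj[v]) {
      if (u > v) { ext.push_back(u); in_nbhd[u] = 1; }
    }
    extend(v, sub, ext, in_nbhd, orb);
    for (int u : adj[v]) in_nbhd[u] = 0;
  }
  adj.clear();
  amat.clear();
  return orb;
}
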