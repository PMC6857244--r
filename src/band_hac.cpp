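#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Adjacency-constrained Ward HAC over precomputed pencil tables.
//
// fwd:  (p+1) x h, row r (0-based) = forward pencil P(r, l) at column l-1
// bwd:  (p+1) x h, row r-1 (0-based) = backward pencil Pbar(r, l)
// full: length h, full pencil P(p, l)
//
// Candidate fusions live in a side array (intervals, prev/next links,
// validity flags); the binary min-heap stores (linkage, key, id) triples
// and is cleaned lazily: stale roots are discarded when they surface.

namespace {

struct Engine {
  const NumericMatrix &fwd, &bwd;
  const NumericVector &full;
  int p, h;

  // side array of candidate fusions
  std::vector<int> fI, fM, fJ, fPrev, fNext;
  std::vector<bool> valid;

  // heap arrays
  std::vector<double> hLink;
  std::vector<int> hKey, hId;
  int n = 0, discards = 0;

  Engine(const NumericMatrix &fwd_, const NumericMatrix &bwd_,
         const NumericVector &full_, int p_, int h_)
      : fwd(fwd_), bwd(bwd_), full(full_), p(p_), h(h_) {
    int cap = 3 * p;
    fI.resize(cap + 1); fM.resize(cap + 1); fJ.resize(cap + 1);
    fPrev.resize(cap + 1); fNext.resize(cap + 1);
    valid.assign(cap + 1, false);
    hLink.reserve(cap); hKey.reserve(cap); hId.reserve(cap);
    hLink.resize(cap); hKey.resize(cap); hId.resize(cap);
  }

  // S(C) for C = [i, j), 1-based half-open
  double intervalSum(int i, int j) const {
    int l = std::min(h, j - i);
    return fwd(j - 1, l - 1) + bwd(i - 1, l - 1) - full[l - 1];
  }

  double delta(int i, int m, int j) const {
    return intervalSum(i, m) / (m - i) + intervalSum(m, j) / (j - m) -
           intervalSum(i, j) / (j - i);
  }

  bool less(int a, int b) const {
    return hLink[a] < hLink[b] || (hLink[a] == hLink[b] && hKey[a] < hKey[b]);
  }

  void swapNodes(int a, int b) {
    std::swap(hLink[a], hLink[b]);
    std::swap(hKey[a], hKey[b]);
    std::swap(hId[a], hId[b]);
  }

  void push(int id, double link, int key) {
    int k = n++;
    hLink[k] = link; hKey[k] = key; hId[k] = id;
    while (k > 0) {
      int par = (k - 1) / 2;
      if (less(k, par)) { swapNodes(k, par); k = par; } else break;
    }
  }

  void popRoot() {
    --n;
    hLink[0] = hLink[n]; hKey[0] = hKey[n]; hId[0] = hId[n];
    int k = 0;
    for (;;) {
      int l = 2 * k + 1, r = l + 1;
      if (l >= n) break;
      int m = (r < n && less(r, l)) ? r : l;
      if (less(m, k)) { swapNodes(k, m); k = m; } else break;
    }
  }

  // pop the minimum active fusion, cleaning stale roots lazily
  int popMinActive(double *linkOut) {
    while (n > 0 && !valid[hId[0]]) { popRoot(); ++discards; }
    if (n == 0) return 0;
    int id = hId[0];
    *linkOut = hLink[0];
    valid[id] = false;
    popRoot();
    return id;
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_band_hac")]]
List cpp_band_hac(NumericMatrix fwd, NumericMatrix bwd, NumericVector full,
                  int p, int h) {
  Engine E(fwd, bwd, full, p, h);

  int nInit = p - 1;
  for (int t = 1; t <= nInit; ++t) {
    E.fI[t] = t; E.fM[t] = t + 1; E.fJ[t] = t + 2;
    E.fPrev[t] = t - 1;
    E.fNext[t] = (t < nInit) ? t + 1 : 0;
    E.valid[t] = true;
    E.push(t, E.delta(t, t + 1, t + 2), t);
  }
  int nextId = nInit + 1;

  NumericMatrix mg(p - 1, 8);
  std::vector<int> clusterStep(p + 1, 0);

  for (int step = 1; step <= p - 1; ++step) {
    double link;
    int id = E.popMinActive(&link);
    if (id == 0) stop("internal error: heap exhausted at step %d", step);
    int i = E.fI[id], m = E.fM[id], j = E.fJ[id];
    int leftRef = (m - i == 1) ? -i : clusterStep[i];
    int rightRef = (j - m == 1) ? -m : clusterStep[m];
    mg(step - 1, 0) = leftRef;  mg(step - 1, 1) = rightRef;
    mg(step - 1, 2) = i;        mg(step - 1, 3) = m;
    mg(step - 1, 4) = j;        mg(step - 1, 5) = link;
    mg(step - 1, 6) = m - i;    mg(step - 1, 7) = j - m;
    clusterStep[i] = step;

    int pv = E.fPrev[id], nx = E.fNext[id];
    if (pv) E.valid[pv] = false;
    if (nx) E.valid[nx] = false;

    int newL = 0, newR = 0;
    if (pv) {                    // merge prev's left cluster with [i, j)
      newL = nextId++;
      E.fI[newL] = E.fI[pv]; E.fM[newL] = i; E.fJ[newL] = j;
    }
    if (nx) {                    // merge [i, j) with next's right cluster
      newR = nextId++;
      E.fI[newR] = i; E.fM[newR] = j; E.fJ[newR] = E.fJ[nx];
    }
    if (newL) {
      E.fPrev[newL] = E.fPrev[pv];
      E.fNext[newL] = newR;      // 0 when the merged cluster is rightmost
      if (E.fPrev[pv]) E.fNext[E.fPrev[pv]] = newL;
      E.valid[newL] = true;
      E.push(newL, E.delta(E.fI[newL], E.fM[newL], E.fJ[newL]), E.fI[newL]);
    }
    if (newR) {
      E.fPrev[newR] = newL;      // 0 when the merged cluster is leftmost
      E.fNext[newR] = E.fNext[nx];
      if (E.fNext[nx]) E.fPrev[E.fNext[nx]] = newR;
      E.valid[newR] = true;
      E.push(newR, E.delta(E.fI[newR], E.fM[newR], E.fJ[newR]), E.fI[newR]);
    }
  }

  return List::create(_["merges"] = mg, _["discards"] = E.discards);
}

// Forward and backward pencil tables of a p x h band matrix, filled by the
// same row-contribution + cumulative-sum recursion as the documented O(ph)
// construction; long-double accumulators keep the cumulative sums accurate.
// [[Rcpp::export(".cpp_pencil_tables")]]
List cpp_pencil_tables(const NumericMatrix& band) {
  const int p = band.nrow(), h = band.ncol();
  NumericMatrix fwd(p + 1, h), bwd(p + 1, h);
  std::vector<double> rp(p), rpRev(p);
  std::vector<double> colRev(p + 1);
  for (int l = 0; l < h; ++l) {
    for (int r = 0; r < p; ++r) {
      if (l == 0) {
        rp[r] = band(r, 0);
        rpRev[r] = band(p - 1 - r, 0);
      } else if (r >= l) {
        rp[r] += 2.0 * band(r - l, l);
        rpRev[r] += 2.0 * band(p - 1 - r, l);
      }
    }
    long double acc = 0.0L, accRev = 0.0L;
    fwd(0, l) = 0.0;
    colRev[0] = 0.0;
    for (int r = 0; r < p; ++r) {
      acc += rp[r];
      accRev += rpRev[r];
      fwd(r + 1, l) = (double)acc;
      colRev[r + 1] = (double)accRev;
    }
    for (int r = 0; r <= p; ++r) bwd(r, l) = colRev[p - r];
  }
  return List::create(_["fwd"] = fwd, _["bwd"] = bwd);
}
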