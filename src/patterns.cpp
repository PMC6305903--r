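#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Closed frequent itemset mining of spatiotemporal spike patterns.
//
// Every window start w (0..n_bins-1) is a transaction holding the items
// (neuron, lag) for which the neuron has a spike in bin w + lag,
// lag in 0..n_lags-1. Item ids are ordered as id = lag * n_neurons + neuron,
// so the minimum item of any pattern whose minimum lag is 0 is a lag-0
// item. Closed itemsets are enumerated LCM-style by prefix-preserving
// closure (ppc) extension; restricting the first extension to lag-0 items
// then enumerates exactly one lag-anchored representative per shift-class
// of patterns, each exactly once. Recursion works on projected databases
// (transactions restricted to locally frequent items), which keeps the
// per-node closure scans proportional to the local problem size.

namespace {

struct Proj {  // projected database: rows parallel to tids, items ascending
  std::vector<int> ptr;  // size rows + 1
  std::vector<int> item;
  int rows() const { return (int)ptr.size() - 1; }
};

struct Miner {
  int min_occ, min_size;
  std::vector<int> cnt;  // per-item scratch counter (always zeroed on exit)
  std::vector<std::vector<int>> out_items;
  std::vector<std::vector<int>> out_tids;

  // Expand the closed set P (occurring at windows tids, projected database
  // proj) by every locally frequent item e > core. At the root (P empty)
  // candidates are restricted to ids < root_max (the lag-0 items).
  void grow(const std::vector<int> &P, const std::vector<int> &tids,
            const Proj &proj, int core, int root_max) {
    const int m = (int)tids.size();
    std::vector<int> touched;
    for (size_t k = 0; k < proj.item.size(); ++k) {
      if (cnt[proj.item[k]]++ == 0) touched.push_back(proj.item[k]);
    }
    std::vector<int> cand;
    for (int e : touched) {
      if (cnt[e] >= min_occ && cnt[e] < m && e > core &&
          (root_max < 0 || e < root_max)) {
        cand.push_back(e);
      }
    }
    if ((int)P.size() + (int)cand.size() < min_size) {
      for (int e : touched) cnt[e] = 0;
      return;
    }
    std::sort(cand.begin(), cand.end());
    // occurrence delivery: per-candidate row lists in one scan of proj
    std::vector<int> pos_ptr(cand.size() + 1, 0);
    for (size_t j = 0; j < cand.size(); ++j) {
      pos_ptr[j + 1] = pos_ptr[j] + cnt[cand[j]];
    }
    for (int e : touched) cnt[e] = 0;
    for (size_t j = 0; j < cand.size(); ++j) cnt[cand[j]] = (int)j + 1;
    std::vector<int> pos_row(pos_ptr.back());
    {
      std::vector<int> fill(pos_ptr.begin(), pos_ptr.end() - 1);
      for (int r = 0; r < proj.rows(); ++r) {
        for (int k = proj.ptr[r]; k < proj.ptr[r + 1]; ++k) {
          const int j = cnt[proj.item[k]];
          if (j > 0) pos_row[fill[j - 1]++] = r;
        }
      }
    }
    for (size_t j = 0; j < cand.size(); ++j) cnt[cand[j]] = 0;

    std::vector<int> touched2, Q, newtids;
    for (size_t j = 0; j < cand.size(); ++j) {
      const int e = cand[j];
      const int s = pos_ptr[j + 1] - pos_ptr[j];
      // closure counts over the rows containing e
      touched2.clear();
      for (int q = pos_ptr[j]; q < pos_ptr[j + 1]; ++q) {
        const int r = pos_row[q];
        for (int k = proj.ptr[r]; k < proj.ptr[r + 1]; ++k) {
          if (cnt[proj.item[k]]++ == 0) touched2.push_back(proj.item[k]);
        }
      }
      Q.clear();
      bool ppc = true;
      int n_ext = 0;
      for (int f : touched2) {
        if (cnt[f] == s) {
          Q.push_back(f);
          if (f < e && !std::binary_search(P.begin(), P.end(), f)) ppc = false;
        } else if (cnt[f] >= min_occ && f > e) {
          ++n_ext;
        }
      }
      if (!ppc) {  // this closed set is reached from a smaller prefix
        for (int f : touched2) cnt[f] = 0;
        continue;
      }
      std::sort(Q.begin(), Q.end());
      newtids.clear();
      for (int q = pos_ptr[j]; q < pos_ptr[j + 1]; ++q) {
        newtids.push_back(tids[pos_row[q]]);
      }
      if ((int)Q.size() >= min_size) {
        out_items.push_back(Q);
        out_tids.push_back(newtids);
      }
      if (n_ext > 0 && (int)Q.size() + n_ext >= min_size) {
        Proj child;  // rows of e, items locally frequent
        child.ptr.assign(1, 0);
        for (int q = pos_ptr[j]; q < pos_ptr[j + 1]; ++q) {
          const int r = pos_row[q];
          for (int k = proj.ptr[r]; k < proj.ptr[r + 1]; ++k) {
            if (cnt[proj.item[k]] >= min_occ) {
              child.item.push_back(proj.item[k]);
            }
          }
          child.ptr.push_back((int)child.item.size());
        }
        for (int f : touched2) cnt[f] = 0;
        grow(Q, newtids, child, e, -1);
      } else {
        for (int f : touched2) cnt[f] = 0;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List mine_patterns_core(List spike_bins, int n_bins, int n_lags,
                        int min_occ, int min_size) {
  const int n_neurons = spike_bins.size();
  const int n_items = n_neurons * n_lags;
  Miner M;
  M.min_occ = min_occ;
  M.min_size = min_size;
  M.cnt.assign(n_items, 0);

  // transaction database; iterating lag (outer) then neuron keeps each
  // window's item list sorted by id = lag * n_neurons + neuron
  std::vector<std::vector<int>> bins(n_neurons);
  std::vector<int> sizes(n_bins, 0);
  for (int n = 0; n < n_neurons; ++n) {
    IntegerVector b = spike_bins[n];
    bins[n].assign(b.begin(), b.end());
    for (int l = 0; l < n_lags; ++l) {
      for (int bb : bins[n]) {
        const int w = bb - l;
        if (w >= 0 && w < n_bins) ++sizes[w];
      }
    }
  }
  Proj db;
  db.ptr.assign(n_bins + 1, 0);
  for (int w = 0; w < n_bins; ++w) db.ptr[w + 1] = db.ptr[w] + sizes[w];
  db.item.assign(db.ptr[n_bins], 0);
  {
    std::vector<int> fill(db.ptr.begin(), db.ptr.end() - 1);
    for (int l = 0; l < n_lags; ++l) {
      for (int n = 0; n < n_neurons; ++n) {
        const int id = l * n_neurons + n;
        for (int bb : bins[n]) {
          const int w = bb - l;
          if (w >= 0 && w < n_bins) db.item[fill[w]++] = id;
        }
      }
    }
  }
  std::vector<int> all_tids(n_bins);
  for (int w = 0; w < n_bins; ++w) all_tids[w] = w;

  // root closure: items present in every window. Such items can only be
  // lag-0 items, so when the closure is nonempty every closed set contains
  // it and is automatically lag-anchored; the root restriction to lag-0
  // extensions applies only when the closure is empty.
  std::vector<int> closure0;
  if (n_bins > 0) {
    for (size_t k = 0; k < db.item.size(); ++k) ++M.cnt[db.item[k]];
    for (int e = 0; e < n_items; ++e) {
      if (M.cnt[e] == n_bins) closure0.push_back(e);
      M.cnt[e] = 0;
    }
    if ((int)closure0.size() >= min_size && n_bins >= min_occ) {
      M.out_items.push_back(closure0);
      M.out_tids.push_back(all_tids);
    }
    const int root_max = closure0.empty() ? n_neurons : -1;
    M.grow(closure0, all_tids, db, -1, root_max);
  }

  const int np = (int)M.out_items.size();
  List items(np), tids(np);
  for (int p = 0; p < np; ++p) {
    items[p] = wrap(M.out_items[p]);
    tids[p] = wrap(M.out_tids[p]);
  }
  return List::create(_["items"] = items, _["tids"] = tids);
}
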