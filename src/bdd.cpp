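// Reduced ordered binary decision diagrams (ROBDD) for symbolic state-set
// manipulation.  Grow-only node store with a unique table (hash consing),
// an ITE computed-table, quantification, conjunctive quantification
// (relational product) and monotone variable renaming.  Node ids are ints;
// 0 and 1 are the terminal constants.  Managers are exposed to R as
// external pointers; all operations are deterministic.

#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct TripleHash {
  std::size_t operator()(const std::array<int, 3> &k) const {
    std::uint64_t h = 1469598103934665603ull;
    for (int v : k) {
      h ^= static_cast<std::uint64_t>(static_cast<std::uint32_t>(v));
      h *= 1099511628211ull;
    }
    return static_cast<std::size_t>(h);
  }
};

struct PairHash {
  std::size_t operator()(const std::array<int, 2> &k) const {
    std::uint64_t h = static_cast<std::uint32_t>(k[0]);
    h = (h << 32) | static_cast<std::uint32_t>(k[1]);
    h *= 0x9E3779B97F4A7C15ull;
    return static_cast<std::size_t>(h ^ (h >> 29));
  }
};

class BddMgr {
public:
  explicit BddMgr(int nvars) : nvars_(nvars) {
    // terminals: id 0 = FALSE, id 1 = TRUE; sentinel var = nvars
    var_ = {nvars, nvars};
    lo_ = {0, 1};
    hi_ = {0, 1};
  }

  int nvars() const { return nvars_; }
  int var(int f) const { return var_[f]; }
  int lo(int f) const { return lo_[f]; }
  int hi(int f) const { return hi_[f]; }
  std::size_t size() const { return var_.size(); }

  int mk(int v, int lo, int hi) {
    if (lo == hi) return lo;
    std::array<int, 3> key = {v, lo, hi};
    auto it = unique_.find(key);
    if (it != unique_.end()) return it->second;
    int id = static_cast<int>(var_.size());
    var_.push_back(v);
    lo_.push_back(lo);
    hi_.push_back(hi);
    unique_.emplace(key, id);
    return id;
  }

  int ithvar(int v) { return mk(v, 0, 1); }

  int ite(int f, int g, int h) {
    if (f == 1) return g;
    if (f == 0) return h;
    if (g == h) return g;
    if (g == 1 && h == 0) return f;
    std::array<int, 3> key = {f, g, h};
    auto it = ite_cache_.find(key);
    if (it != ite_cache_.end()) return it->second;
    int v = std::min(var_[f], std::min(var_[g], var_[h]));
    int f0 = (var_[f] == v) ? lo_[f] : f, f1 = (var_[f] == v) ? hi_[f] : f;
    int g0 = (var_[g] == v) ? lo_[g] : g, g1 = (var_[g] == v) ? hi_[g] : g;
    int h0 = (var_[h] == v) ? lo_[h] : h, h1 = (var_[h] == v) ? hi_[h] : h;
    int r = mk(v, ite(f0, g0, h0), ite(f1, g1, h1));
    ite_cache_.emplace(key, r);
    return r;
  }

  int bnot(int f) { return ite(f, 0, 1); }
  int band(int f, int g) { return ite(f, g, 0); }
  int bor(int f, int g) { return ite(f, 1, g); }
  int bxor(int f, int g) { return ite(f, bnot(g), g); }

  // existential quantification over the variables flagged in mask
  int exists(int f, const std::vector<char> &mask,
             std::unordered_map<int, int> &cache) {
    if (f <= 1) return f;
    auto it = cache.find(f);
    if (it != cache.end()) return it->second;
    int v = var_[f];
    int l = exists(lo_[f], mask, cache);
    int h = exists(hi_[f], mask, cache);
    int r = mask[v] ? bor(l, h) : mk(v, l, h);
    cache.emplace(f, r);
    return r;
  }

  // exists mask . (f & g) without building the full conjunction
  int and_exists(int f, int g, const std::vector<char> &mask,
                 std::unordered_map<std::array<int, 2>, int, PairHash> &cache,
                 std::unordered_map<int, int> &ecache) {
    if (f == 0 || g == 0) return 0;
    if (f == 1 && g == 1) return 1;
    if (f == 1) return exists(g, mask, ecache);
    if (g == 1) return exists(f, mask, ecache);
    if (f == g) return exists(f, mask, ecache);
    std::array<int, 2> key = {std::min(f, g), std::max(f, g)};
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    int v = std::min(var_[f], var_[g]);
    int f0 = (var_[f] == v) ? lo_[f] : f, f1 = (var_[f] == v) ? hi_[f] : f;
    int g0 = (var_[g] == v) ? lo_[g] : g, g1 = (var_[g] == v) ? hi_[g] : g;
    int r;
    if (mask[v]) {
      int l = and_exists(f0, g0, mask, cache, ecache);
      if (l == 1) {
        r = 1;
      } else {
        r = bor(l, and_exists(f1, g1, mask, cache, ecache));
      }
    } else {
      r = mk(v, and_exists(f0, g0, mask, cache, ecache),
             and_exists(f1, g1, mask, cache, ecache));
    }
    cache.emplace(key, r);
    return r;
  }

  // rename variables through a strictly monotone map (on the support of f)
  int permute(int f, const std::vector<int> &perm,
              std::unordered_map<int, int> &cache) {
    if (f <= 1) return f;
    auto it = cache.find(f);
    if (it != cache.end()) return it->second;
    int r = mk(perm[var_[f]], permute(lo_[f], perm, cache),
               permute(hi_[f], perm, cache));
    cache.emplace(f, r);
    return r;
  }

  int restrict1(int f, int v, int val, std::unordered_map<int, int> &cache) {
    if (f <= 1 || var_[f] > v) return f;
    auto it = cache.find(f);
    if (it != cache.end()) return it->second;
    int r;
    if (var_[f] == v) {
      r = val ? hi_[f] : lo_[f];
    } else {
      r = mk(var_[f], restrict1(lo_[f], v, val, cache),
             restrict1(hi_[f], v, val, cache));
    }
    cache.emplace(f, r);
    return r;
  }

  bool eval(int f, const std::vector<char> &assign) const {
    while (f > 1) f = assign[var_[f]] ? hi_[f] : lo_[f];
    return f == 1;
  }

  // lexicographically minimal satisfying assignment (don't-cares -> 0)
  std::vector<int> sat_one(int f) const {
    std::vector<int> a(nvars_, 0);
    while (f > 1) {
      if (lo_[f] != 0) {
        f = lo_[f];
      } else {
        a[var_[f]] = 1;
        f = hi_[f];
      }
    }
    return a;
  }

  double sat_count(int f, int nsupp,
                   std::unordered_map<int, double> &cache) const {
    if (f == 0) return 0.0;
    if (f == 1) return 1.0;  // scaled below by caller across all vars
    auto it = cache.find(f);
    if (it != cache.end()) return it->second;
    double l = sat_count(lo_[f], nsupp, cache) *
               std::pow(2.0, var_[lo_[f]] - var_[f] - 1);
    double h = sat_count(hi_[f], nsupp, cache) *
               std::pow(2.0, var_[hi_[f]] - var_[f] - 1);
    double r = l + h;
    cache.emplace(f, r);
    return r;
  }

private:
  int nvars_;
  std::vector<int> var_, lo_, hi_;
  std::unordered_map<std::array<int, 3>, int, TripleHash> unique_;
  std::unordered_map<std::array<int, 3>, int, TripleHash> ite_cache_;
};

std::vector<char> mask_from(const IntegerVector &vars, int nvars) {
  std::vector<char> mask(nvars, 0);
  for (int v : vars) {
    if (v < 0 || v >= nvars) stop("variable index out of range");
    mask[v] = 1;
  }
  return mask;
}

}  // namespace

// [[Rcpp::export(name = ".bdd_manager")]]
SEXP bdd_manager(int nvars) {
  if (nvars < 1) stop("need at least one variable");
  XPtr<BddMgr> p(new BddMgr(nvars), true);
  return p;
}

// [[Rcpp::export(name = ".bdd_nvars")]]
int bdd_nvars(SEXP mgr) { return XPtr<BddMgr>(mgr)->nvars(); }

// [[Rcpp::export(name = ".bdd_size")]]
double bdd_size(SEXP mgr) {
  return static_cast<double>(XPtr<BddMgr>(mgr)->size());
}

// [[Rcpp::export(name = ".bdd_ithvar")]]
int bdd_ithvar(SEXP mgr, int v) {
  XPtr<BddMgr> m(mgr);
  if (v < 0 || v >= m->nvars()) stop("variable index out of range");
  return m->ithvar(v);
}

// [[Rcpp::export(name = ".bdd_not")]]
int bdd_not(SEXP mgr, int f) { return XPtr<BddMgr>(mgr)->bnot(f); }

// [[Rcpp::export(name = ".bdd_and")]]
int bdd_and(SEXP mgr, int f, int g) { return XPtr<BddMgr>(mgr)->band(f, g); }

// [[Rcpp::export(name = ".bdd_or")]]
int bdd_or(SEXP mgr, int f, int g) { return XPtr<BddMgr>(mgr)->bor(f, g); }

// [[Rcpp::export(name = ".bdd_xor")]]
int bdd_xor(SEXP mgr, int f, int g) { return XPtr<BddMgr>(mgr)->bxor(f, g); }

// [[Rcpp::export(name = ".bdd_ite")]]
int bdd_ite(SEXP mgr, int f, int g, int h) {
  return XPtr<BddMgr>(mgr)->ite(f, g, h);
}

// [[Rcpp::export(name = ".bdd_exists")]]
int bdd_exists(SEXP mgr, int f, IntegerVector vars) {
  XPtr<BddMgr> m(mgr);
  std::vector<char> mask = mask_from(vars, m->nvars());
  std::unordered_map<int, int> cache;
  return m->exists(f, mask, cache);
}

// [[Rcpp::export(name = ".bdd_and_exists")]]
int bdd_and_exists(SEXP mgr, int f, int g, IntegerVector vars) {
  XPtr<BddMgr> m(mgr);
  std::vector<char> mask = mask_from(vars, m->nvars());
  std::unordered_map<std::array<int, 2>, int, PairHash> cache;
  std::unordered_map<int, int> ecache;
  return m->and_exists(f, g, mask, cache, ecache);
}

// [[Rcpp::export(name = ".bdd_permute")]]
int bdd_permute(SEXP mgr, int f, IntegerVector perm) {
  XPtr<BddMgr> m(mgr);
  if (perm.size() != m->nvars()) stop("permutation length mismatch");
  std::vector<int> p(perm.begin(), perm.end());
  std::unordered_map<int, int> cache;
  return m->permute(f, p, cache);
}

// [[Rcpp::export(name = ".bdd_restrict")]]
int bdd_restrict(SEXP mgr, int f, int v, int val) {
  XPtr<BddMgr> m(mgr);
  if (v < 0 || v >= m->nvars()) stop("variable index out of range");
  std::unordered_map<int, int> cache;
  return m->restrict1(f, v, val != 0, cache);
}

// [[Rcpp::export(name = ".bdd_eval")]]
bool bdd_eval(SEXP mgr, int f, IntegerVector assign) {
  XPtr<BddMgr> m(mgr);
  if (assign.size() != m->nvars()) stop("assignment length mismatch");
  std::vector<char> a(assign.begin(), assign.end());
  return m->eval(f, a);
}

// [[Rcpp::export(name = ".bdd_sat_one")]]
IntegerVector bdd_sat_one(SEXP mgr, int f) {
  XPtr<BddMgr> m(mgr);
  if (f == 0) stop("unsatisfiable BDD has no satisfying assignment");
  std::vector<int> a = m->sat_one(f);
  return IntegerVector(a.begin(), a.end());
}

// [[Rcpp::export(name = ".bdd_sat_count")]]
double bdd_sat_count(SEXP mgr, int f) {
  XPtr<BddMgr> m(mgr);
  if (f == 0) return 0.0;
  std::unordered_map<int, double> cache;
  // treat the root as if preceded by a virtual variable at level -1
  double c = m->sat_count(f, m->nvars(), cache);
  return c * std::pow(2.0, m->var(f));
}

// Evaluate membership of many packed assignments at once; `assigns` is a
// row-major matrix (n x nvars) of 0/1.
// [[Rcpp::export(name = ".bdd_eval_many")]]
LogicalVector bdd_eval_many(SEXP mgr, int f, IntegerMatrix assigns) {
  XPtr<BddMgr> m(mgr);
  if (assigns.ncol() != m->nvars()) stop("assignment length mismatch");
  int n = assigns.nrow();
  LogicalVector out(n);
  std::vector<char> a(m->nvars());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m->nvars(); ++j) a[j] = assigns(i, j) != 0;
    out[i] = m->eval(f, a);
  }
  return out;
}
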