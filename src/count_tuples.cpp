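// Exact tail counting for the rank-product statistic under the
// with-replacement null (k i.i.d. ranks uniform on {1..n}).
//
// T(k, n, x) = #{ (r_1..r_k) in {1..n}^k : prod r_i <= x }
//            = sum_{r=1}^{min(n,x)} T(k-1, n, floor(x/r)),  T(0, n, x) = [x >= 1]
//
// The recursion is memoized on (level, floor value); floor values collapse
// because floor(floor(x/a)/b) == floor(x/(a*b)).  Saturated calls
// (x >= n^level) return n^level without recursing, level 1 has a closed
// form, level 2 is a single hyperbola sum, and equal quotients floor(x/r)
// are enumerated in blocks.
//
// The bound x is carried in 64-bit integers when it fits (the common case)
// and in unsigned __int128 otherwise (exact for x < 2^127).  Counts are
// accumulated in long double (64-bit mantissa): exact below 2^64 and within
// ~1e-18 relative error beyond, which exceeds the precision of the returned
// double p-value.  Two caps bound the work: `budget` on memoized states
// (distinct floor values across levels) and `ops_cap` on elementary loop
// iterations.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

typedef unsigned __int128 u128;

namespace {

struct BudgetExceeded {};

const u128 U128_MAX = ~(u128)0;

long double ld128(u128 v) {
  const long double two64 = 18446744073709551616.0L;
  return (long double)(uint64_t)(v >> 64) * two64 + (long double)(uint64_t)v;
}

inline long double ldof(uint64_t v) { return (long double)v; }
inline long double ldof(u128 v) { return ld128(v); }

// parse a non-negative decimal integer; returns false on overflow/garbage
bool parse_u128(const std::string& s, u128& out) {
  if (s.empty()) return false;
  u128 acc = 0;
  for (char c : s) {
    if (c < '0' || c > '9') return false;
    unsigned d = (unsigned)(c - '0');
    if (acc > (U128_MAX - d) / 10) return false;
    acc = acc * 10 + d;
  }
  out = acc;
  return true;
}

struct U128Hash {
  size_t operator()(const u128& v) const {
    uint64_t lo = (uint64_t)v, hi = (uint64_t)(v >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL ^
                 (hi + 0x9E3779B97F4A7C15ULL + (lo << 6) + (lo >> 2));
    return (size_t)h;
  }
};

template <typename U> struct HashFor { typedef std::hash<U> type; };
template <> struct HashFor<u128> { typedef U128Hash type; };

template <typename U>
class TupleCounter {
public:
  TupleCounter(int k, int n, double budget, double ops_cap)
      : k_(k), n_(n), budget_(budget), ops_cap_(ops_cap), states_(0), ops_(0) {
    npow_.resize(k + 1);
    npow_ld_.resize(k + 1);
    npow_[0] = 1;
    npow_ld_[0] = 1.0L;
    const U u_max = ~(U)0;
    bool sat = false;
    for (int j = 1; j <= k; ++j) {
      npow_ld_[j] = npow_ld_[j - 1] * (long double)n;
      if (sat || npow_[j - 1] > u_max / (U)n) {
        sat = true;
        npow_[j] = u_max;  // saturate: any representable x is < n^j
      } else {
        npow_[j] = npow_[j - 1] * (U)n;
      }
    }
    memo_.resize(k + 1);
  }

  long double count(int level, U x) {
    if (x == 0) return 0.0L;
    if (x >= npow_[level]) return npow_ld_[level];
    if (level == 1) return ldof(x);        // x < n here, count = x
    if (level == 2) return count2(x);
    auto& tab = memo_[level];
    auto it = tab.find(x);
    if (it != tab.end()) return it->second;
    long double total = 0.0L;
    U lim = std::min<U>((U)n_, x);
    for (U r = 1; r <= lim;) {
      U q = x / r;
      U rmax = std::min<U>(x / q, lim);
      total += ldof((U)(rmax - r + 1)) * count(level - 1, q);
      r = rmax + 1;
      tick();
    }
    tab.emplace(x, total);
    if (++states_ > budget_) throw BudgetExceeded();
    return total;
  }

  // level 2 closed form: sum_{r=1}^{min(n,x)} min(n, floor(x/r)), x < n^2
  long double count2(U x) {
    auto it = memo_[2].find(x);
    if (it != memo_[2].end()) return it->second;
    long double total = 0.0L;
    U lim = std::min<U>((U)n_, x);
    U r = 1;
    U r_big = x / (U)n_;  // for r <= r_big, floor(x/r) >= n
    if (r_big >= 1) {
      U hi = std::min<U>(r_big, lim);
      total += ldof(hi) * (long double)n_;
      r = hi + 1;
    }
    while (r <= lim) {
      U q = x / r;
      U rmax = std::min<U>(x / q, lim);
      total += ldof((U)(rmax - r + 1)) * ldof(q);
      r = rmax + 1;
      tick();
    }
    memo_[2].emplace(x, total);
    if (++states_ > budget_) throw BudgetExceeded();
    return total;
  }

  void tick() {
    if (++ops_ > ops_cap_) throw BudgetExceeded();
  }

  double states() const { return states_; }
  long double npow_ld(int j) const { return npow_ld_[j]; }
  U npow(int j) const { return npow_[j]; }

private:
  int k_, n_;
  double budget_, ops_cap_, states_, ops_;
  std::vector<U> npow_;
  std::vector<long double> npow_ld_;
  std::vector<std::unordered_map<U, long double, typename HashFor<U>::type>> memo_;
};

template <typename U>
Rcpp::List run_counter(int k, int n, U x, double budget, double ops_cap) {
  TupleCounter<U> tc(k, n, budget, ops_cap);
  long double cnt;
  try {
    cnt = tc.count(k, x);
  } catch (BudgetExceeded&) {
    return Rcpp::List::create(
      Rcpp::Named("ok") = false,
      Rcpp::Named("reason") = "budget",
      Rcpp::Named("states") = tc.states());
  }
  double p, log_p;
  if (x >= tc.npow(k)) {
    p = 1.0;
    log_p = 0.0;
  } else {
    p = (double)(cnt / tc.npow_ld(k));
    log_p = (cnt > 0.0L)
      ? (double)(logl(cnt) - (long double)k * logl((long double)n))
      : R_NegInf;
  }
  return Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("count") = (double)cnt,
    Rcpp::Named("p") = p,
    Rcpp::Named("log_p") = log_p,
    Rcpp::Named("states") = tc.states());
}

}  // namespace

// [[Rcpp::export(name = ".rp_count_leq")]]
Rcpp::List rp_count_leq(int k, int n, std::string x_dec, double budget,
                        double ops_cap = 2e8) {
  if (k < 0) Rcpp::stop("k must be >= 0");
  if (n < 1) Rcpp::stop("n must be >= 1");
  u128 x;
  if (!parse_u128(x_dec, x)) {
    return Rcpp::List::create(
      Rcpp::Named("ok") = false,
      Rcpp::Named("reason") = "magnitude");
  }
  if (k == 0) {
    double c0 = (x >= 1) ? 1.0 : 0.0;
    return Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("count") = c0,
      Rcpp::Named("p") = c0, Rcpp::Named("log_p") = (c0 > 0 ? 0.0 : R_NegInf),
      Rcpp::Named("states") = 0.0);
  }
  // 64-bit fast path whenever x (hence every floor quotient) fits
  if ((x >> 63) == 0) {
    return run_counter<uint64_t>(k, n, (uint64_t)x, budget, ops_cap);
  }
  return run_counter<u128>(k, n, x, budget, ops_cap);
}

// product of integer ranks: `fits128` says whether it fits u128 (the exact
// counter's domain); `dec` is always the exact decimal value (base-1e9
// long multiplication when the product overflows 128 bits)
// [[Rcpp::export(name = ".rp_product_dec")]]
Rcpp::List rp_product_dec(Rcpp::IntegerVector ranks) {
  u128 prod = 1;
  bool fits = true;
  for (int i = 0; i < ranks.size(); ++i) {
    u128 r = (u128)(uint64_t)ranks[i];
    if (r == 0) Rcpp::stop("ranks must be >= 1");
    if (fits && prod > U128_MAX / r) { fits = false; break; }
    if (fits) prod *= r;
  }
  std::string dec;
  if (fits) {
    while (prod > 0) {
      dec.push_back('0' + (char)(uint64_t)(prod % 10));
      prod /= 10;
    }
    if (dec.empty()) dec = "1";
    std::reverse(dec.begin(), dec.end());
  } else {
    const uint64_t base = 1000000000ULL;  // 1e9
    std::vector<uint64_t> limbs{1};       // little-endian base-1e9
    for (int i = 0; i < ranks.size(); ++i) {
      uint64_t r = (uint64_t)ranks[i];
      uint64_t carry = 0;
      for (size_t j = 0; j < limbs.size(); ++j) {
        uint64_t v = limbs[j] * r + carry;  // < 1e9 * 2^31 + carry, fits
        limbs[j] = v % base;
        carry = v / base;
      }
      while (carry > 0) {
        limbs.push_back(carry % base);
        carry /= base;
      }
    }
    char buf[16];
    snprintf(buf, sizeof(buf), "%llu",
             (unsigned long long)limbs.back());
    dec = buf;
    for (size_t j = limbs.size() - 1; j-- > 0;) {
      snprintf(buf, sizeof(buf), "%09llu", (unsigned long long)limbs[j]);
      dec += buf;
    }
  }
  return Rcpp::List::create(Rcpp::Named("ok") = fits,
                            Rcpp::Named("dec") = dec);
}
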