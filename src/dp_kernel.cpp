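#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
using namespace Rcpp;

// Gray-code chunk evaluation for one column of the wMEC dynamic program.
//
// Enumerates bipartition masks of the c active reads for ranks in
// [rank_lo, rank_hi) of the binary-reflected Gray sequence, maintaining the
// four part costs (make part R/S all-0/all-1) with a constant-time update
// per rank: consecutive Gray masks differ in one bit, i.e. a single read
// moves between parts, and a read holds at most one call per column.
//
// Bit k of a mask gives the part of the k-th active read. With halve = true
// the first active read is pinned to part 0 and ranks enumerate the reduced
// (c-1)-bit space; each evaluation also records the complementary mask,
// whose cumulative cost is identical by the R/S swap symmetry, so the
// emitted tables match full enumeration bit for bit.
//
// inh_slots / inh_min carry the projection table of the previous column
// boundary (minimum inherited cost per assignment of the shared reads);
// out_slots names the reads shared with the next column, for which local
// per-key minima (and smallest argmin mask) are accumulated.
//
// [[Rcpp::export]]
List eval_chunk_kernel(int c, double rank_lo, double rank_hi,
                       IntegerVector call_slot, IntegerVector call_allele,
                       NumericVector call_weight,
                       IntegerVector inh_slots, NumericVector inh_min,
                       IntegerVector out_slots,
                       bool all_het, bool halve) {
  if (c < 0 || c > 30) stop("coverage out of range for mask enumeration");
  const int shift = halve ? 1 : 0;
  const int nb = c - shift;           // enumerated bits
  if (nb < 0) stop("cannot halve a column with no active reads");
  const int64_t space = 1LL << nb;
  const int64_t lo = (int64_t)rank_lo, hi = (int64_t)rank_hi;
  if (lo < 0 || hi > space || lo > hi)
    stop("rank range outside [0, 2^bits)");

  // slot -> call lookup (at most one call per read per column)
  std::vector<char> has(c, 0);
  std::vector<int> al(c, 0);
  std::vector<double> wt(c, 0.0);
  for (int i = 0; i < call_slot.size(); ++i) {
    int s = call_slot[i];
    if (s < 0 || s >= c) stop("call slot out of range");
    if (has[s]) stop("duplicate call for one read at one column");
    has[s] = 1; al[s] = call_allele[i]; wt[s] = call_weight[i];
  }
  const int s_inh = inh_slots.size();
  const int s_out = out_slots.size();
  if ((int64_t)inh_min.size() != (1LL << s_inh))
    stop("inherited table length must be 2^|shared|");
  std::vector<int> inh_bit(c, -1), out_bit(c, -1);
  for (int i = 0; i < s_inh; ++i) inh_bit[inh_slots[i]] = i;
  for (int i = 0; i < s_out; ++i) out_bit[out_slots[i]] = i;
  const int64_t inh_full = (1LL << s_inh) - 1;
  const int64_t out_full = (1LL << s_out) - 1;
  const int64_t mask_full = (1LL << c) - 1;

  const int64_t n_ranks = hi - lo;
  const int per_rank = halve ? 2 : 1;
  IntegerVector slice_masks(n_ranks * per_rank);
  NumericVector slice_costs(n_ranks * per_rank);
  // sparse local table: only keys this chunk touches (at most 2 per rank)
  std::unordered_map<int64_t, std::pair<double, int> > loc;
  loc.reserve((size_t)(n_ranks * per_rank));

  // chunk entry point: initialise part costs from scratch at the first mask
  int64_t g = lo ^ (lo >> 1);
  int64_t mask = g << shift;
  double w_to0[2] = {0.0, 0.0};       // cost of making part p all-0
  double w_to1[2] = {0.0, 0.0};       // cost of making part p all-1
  for (int s = 0; s < c; ++s) {
    if (!has[s]) continue;
    int p = (mask >> s) & 1;
    if (al[s] == 1) w_to0[p] += wt[s]; else w_to1[p] += wt[s];
  }
  int64_t ikey = 0, okey = 0;
  for (int i = 0; i < s_inh; ++i)
    ikey |= ((mask >> inh_slots[i]) & 1) << i;
  for (int i = 0; i < s_out; ++i)
    okey |= ((mask >> out_slots[i]) & 1) << i;

  int64_t out_i = 0;
  for (int64_t t = lo; t < hi; ++t) {
    double local = all_het
      ? std::min(w_to1[0] + w_to0[1], w_to0[0] + w_to1[1])
      : std::min(w_to0[0], w_to1[0]) + std::min(w_to0[1], w_to1[1]);
    double total = local + inh_min[ikey];
    slice_masks[out_i] = (int)mask;
    slice_costs[out_i] = total;
    ++out_i;
    {
      auto it = loc.find(okey);
      if (it == loc.end()) loc.emplace(okey, std::make_pair(total, (int)mask));
      else if (total < it->second.first ||
               (total == it->second.first && (int)mask < it->second.second))
        it->second = std::make_pair(total, (int)mask);
    }
    if (halve) {
      // complementary mask: same local cost by symmetry; inherited cost
      // read at the complemented key (equal when the inherited table is
      // itself symmetric, as tables built this way are)
      int64_t cmask = (~mask) & mask_full;
      int64_t cikey = (~ikey) & inh_full;
      int64_t cokey = (~okey) & out_full;
      double ctotal = local + inh_min[cikey];
      slice_masks[out_i] = (int)cmask;
      slice_costs[out_i] = ctotal;
      ++out_i;
      auto it = loc.find(cokey);
      if (it == loc.end())
        loc.emplace(cokey, std::make_pair(ctotal, (int)cmask));
      else if (ctotal < it->second.first ||
               (ctotal == it->second.first && (int)cmask < it->second.second))
        it->second = std::make_pair(ctotal, (int)cmask);
    }
    if (t + 1 < hi) {
      // Gray step: the changed bit is the lowest set bit of t+1
      int k0 = __builtin_ctzll((uint64_t)(t + 1));
      int k = k0 + shift;
      mask ^= (1LL << k);
      if (has[k]) {
        int pnew = (mask >> k) & 1, pold = 1 - pnew;
        if (al[k] == 1) { w_to0[pold] -= wt[k]; w_to0[pnew] += wt[k]; }
        else            { w_to1[pold] -= wt[k]; w_to1[pnew] += wt[k]; }
      }
      if (inh_bit[k] >= 0) ikey ^= (1LL << inh_bit[k]);
      if (out_bit[k] >= 0) okey ^= (1LL << out_bit[k]);
    }
  }

  IntegerVector loc_keys(loc.size());
  NumericVector loc_min(loc.size());
  IntegerVector loc_arg(loc.size());
  int64_t i = 0;
  for (auto &kv : loc) {
    loc_keys[i] = (int)kv.first;
    loc_min[i] = kv.second.first;
    loc_arg[i] = kv.second.second;
    ++i;
  }
  return List::create(_["masks"] = slice_masks, _["costs"] = slice_costs,
                      _["local_keys"] = loc_keys, _["local_min"] = loc_min,
                      _["local_argmin"] = loc_arg,
                      _["evaluations"] = (double)n_ranks);
}
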