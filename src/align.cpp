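#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// Banded unit-cost global alignment with traceback (Gotoh three-state DP).
//
// Costs are unit edit costs scaled by SCALE with a +1 epsilon for opening a
// gap: among all unit-cost-optimal alignments the DP therefore returns one
// with the fewest gap events, so a planted contiguous indel is reported as
// one operation instead of being scattered through coincidentally matching
// bases. The epsilon can never change the unit-cost optimum as long as the
// number of gap events stays below SCALE.
//
// Query a (rows), target b (columns). Offset d = j - i is restricted to
// [lo, hi] where lo = min(0, n - m) - extra, hi = max(0, n - m) + extra.
// With extra >= max(m, n) the band covers the full matrix and the result is
// exact. A column where either base is 'N' costs 0 and is classified 'n'
// (ambiguous); matches '='; mismatches 'X'; insertion-in-query 'I' (query
// base only); deletion-in-query 'D' (target base only).
//
// Returns list(dist = unit-cost edit distance, ops = per-column codes).
// [[Rcpp::export]]
List cpp_edit_align(std::string a, std::string b, double extra) {
  const int m = (int)a.size(), n = (int)b.size();
  const long long INF = 1LL << 58;
  const long long SCALE = 1LL << 20, OPEN = 1;

  long long ex = (long long)extra;
  long long lo = std::min(0, n - m) - ex;
  long long hi = std::max(0, n - m) + ex;
  if (lo < -m) lo = -m;
  if (hi > n) hi = n;
  const long long W = hi - lo + 1;  // band width in offset space

  // memory guard: traceback is (m+1) x W bytes
  double bytes = (double)(m + 1) * (double)W;
  if (bytes > 1.5e9)
    stop("alignment band too large (%.0f cells); reduce input or band", bytes);

  // rolling rows for the three states
  std::vector<long long> Mp((size_t)W, INF), Mc((size_t)W, INF);
  std::vector<long long> Xp((size_t)W, INF), Xc((size_t)W, INF);  // Ix: D, left
  std::vector<long long> Yp((size_t)W, INF), Yc((size_t)W, INF);  // Iy: I, up
  // tb byte per cell: bits 0-1 = M diag source (0 M, 1 Ix, 2 Iy),
  // bit 2 = Ix extends (else opens), bit 3 = Iy extends (else opens)
  std::vector<uint8_t> tb((size_t)(m + 1) * (size_t)W, 0);

  // row 0: only deletions (Ix) possible
  for (long long d = lo; d <= hi; ++d) {
    long long j = d;
    if (j < 0 || j > n) continue;
    if (j == 0) {
      Mp[(size_t)(d - lo)] = 0;
    } else {
      Xp[(size_t)(d - lo)] = OPEN + SCALE * j;
      if (j > 1) tb[(size_t)(d - lo)] |= 4;  // extend
    }
  }

  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), INF);
    std::fill(Xc.begin(), Xc.end(), INF);
    std::fill(Yc.begin(), Yc.end(), INF);
    uint8_t* tbrow = &tb[(size_t)i * (size_t)W];
    for (long long d = lo; d <= hi; ++d) {
      long long j = (long long)i + d;
      if (j < 0 || j > n) continue;
      uint8_t byte = 0;
      // M: diagonal from (i-1, j-1) = previous row, same offset
      if (j >= 1) {
        char ca = a[(size_t)(i - 1)], cb = b[(size_t)(j - 1)];
        long long cost = (ca == cb || ca == 'N' || cb == 'N') ? 0 : SCALE;
        long long vm = Mp[(size_t)(d - lo)];
        long long vx = Xp[(size_t)(d - lo)];
        long long vy = Yp[(size_t)(d - lo)];
        long long best = vm; uint8_t src = 0;
        if (vx < best) { best = vx; src = 1; }
        if (vy < best) { best = vy; src = 2; }
        if (best < INF) {
          Mc[(size_t)(d - lo)] = best + cost;
          byte |= src;
        }
      }
      // Ix (deletion, consume target): from (i, j-1) = current row, d-1
      if (d - 1 >= lo && j >= 1) {
        long long op = Mc[(size_t)(d - 1 - lo)];
        long long ext = Xc[(size_t)(d - 1 - lo)];
        long long vopen = (op >= INF) ? INF : op + OPEN + SCALE;
        long long vext = (ext >= INF) ? INF : ext + SCALE;
        if (vext < vopen) {
          Xc[(size_t)(d - lo)] = vext;
          byte |= 4;
        } else if (vopen < INF) {
          Xc[(size_t)(d - lo)] = vopen;
        }
      }
      // Iy (insertion, consume query): from (i-1, j) = previous row, d+1
      if (d + 1 <= hi) {
        long long op = Mp[(size_t)(d + 1 - lo)];
        long long ext = Yp[(size_t)(d + 1 - lo)];
        long long vopen = (op >= INF) ? INF : op + OPEN + SCALE;
        long long vext = (ext >= INF) ? INF : ext + SCALE;
        if (vext < vopen) {
          Yc[(size_t)(d - lo)] = vext;
          byte |= 8;
        } else if (vopen < INF) {
          Yc[(size_t)(d - lo)] = vopen;
        }
      }
      tbrow[(size_t)(d - lo)] = byte;
    }
    std::swap(Mp, Mc);
    std::swap(Xp, Xc);
    std::swap(Yp, Yc);
  }

  long long dfin = (long long)n - (long long)m;
  if (dfin < lo || dfin > hi) stop("final cell outside band");
  long long vm = Mp[(size_t)(dfin - lo)];
  long long vx = Xp[(size_t)(dfin - lo)];
  long long vy = Yp[(size_t)(dfin - lo)];
  int state = 0;  // 0 M, 1 Ix, 2 Iy
  long long best = vm;
  if (vx < best) { best = vx; state = 1; }
  if (vy < best) { best = vy; state = 2; }
  if (best >= INF) stop("no path within band");
  long long dist = best / SCALE;  // epsilon opens stay below SCALE

  // traceback
  std::string ops;
  ops.reserve((size_t)(m + n));
  int i = m;
  long long j = n;
  while (i > 0 || j > 0) {
    uint8_t byte = tb[(size_t)i * (size_t)W + (size_t)(j - i - lo)];
    if (state == 0) {
      char ca = a[(size_t)(i - 1)], cb = b[(size_t)(j - 1)];
      if (ca == 'N' || cb == 'N') ops.push_back('n');
      else if (ca == cb) ops.push_back('=');
      else ops.push_back('X');
      state = byte & 3;
      --i; --j;
    } else if (state == 1) {
      ops.push_back('D');
      state = (byte & 4) ? 1 : 0;
      --j;
    } else {
      ops.push_back('I');
      state = (byte & 8) ? 2 : 0;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["dist"] = (double)dist, _["ops"] = ops);
}

// Positions (1-based, per string) of the next identical k-mer occurrence
// distance for each k-mer start, or 0 when the k-mer does not recur
// downstream within max_period. Used for satellite periodicity.
// [[Rcpp::export]]
IntegerVector cpp_next_kmer_distance(CharacterVector kmers, int max_period) {
  int n = kmers.size();
  IntegerVector out(n, 0);
  std::unordered_map<std::string, int> last;  // kmer -> last index (right-to-left scan)
  last.reserve((size_t)n * 2);
  for (int i = n - 1; i >= 0; --i) {
    std::string k = as<std::string>(kmers[i]);
    auto it = last.find(k);
    if (it != last.end()) {
      int d = it->second - i;
      if (d <= max_period) out[i] = d;
    }
    last[k] = i;
  }
  return out;
}
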