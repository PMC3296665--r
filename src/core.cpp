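#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// small utilities
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1;
  case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// encode k-mer starting at pos (assumes ACGT); returns false if invalid
static inline bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp(as<std::string>(x[i]));
  return out;
}

// ---------------------------------------------------------------------------
// error model: homopolymer re-call + positional substitutions + bg indels
// ---------------------------------------------------------------------------

// Applies the flow-cycle error model to a batch of sequences.
// prof: substitution probability sampled on relative position (index by
//       emitted position / source length).  sigma0/sigma1: homopolymer
//       length-call noise sd = sigma0 + sigma1 * L.  bg_indel: per-base
//       indel probability outside homopolymers (runs of length 1).
// max_out[i]: truncate emitted sequence at this many bases (NA = no cap).
// [[Rcpp::export]]
List cpp_apply_errors(CharacterVector seqs, NumericVector prof,
                      double sigma0, double sigma1, double bg_indel,
                      IntegerVector max_out) {
  int n = seqs.size();
  int np = prof.size();
  CharacterVector out_seq(n);
  IntegerVector n_sub(n), n_ins(n), n_del(n), src_used(n);

  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int len = (int)s.size();
    int cap = max_out[r];
    bool capped = !IntegerVector::is_na(cap);
    std::string out;
    out.reserve(len + 16);
    int sub = 0, ins = 0, del = 0, used = 0;
    bool hit_cap = false;

    int i = 0;
    while (i < len && !hit_cap) {
      char base = s[i];
      int L = 1;
      while (i + L < len && s[i + L] == base) ++L;

      int obs = L;
      double sig = sigma0 + sigma1 * L;
      if (sig > 0) {
        obs = (int)std::lround(R::rnorm((double)L, sig));
        if (obs < 0) obs = 0;
      }
      int emit_real = std::min(L, obs);
      int dels = L - emit_real;
      int inss = obs > L ? obs - L : 0;
      bool bg_ins = false;
      if (L == 1 && bg_indel > 0 && obs == 1) {
        double u = R::unif_rand();
        if (u < bg_indel / 2.0) { emit_real = 0; dels = 1; }
        else if (u < bg_indel) { inss = 1; bg_ins = true; }
      }

      int denom = capped ? std::min(cap, len) : len;
      for (int t = 0; t < emit_real; ++t) {
        if (capped && (int)out.size() >= cap) { hit_cap = true; break; }
        int pidx = denom > 0 ? (int)((double)out.size() / (double)denom * np) : 0;
        if (pidx >= np) pidx = np - 1;
        char b = base;
        if (prof[pidx] > 0 && R::unif_rand() < prof[pidx]) {
          const char* alt = "ACGT";
          char nb;
          do { nb = alt[(int)(R::unif_rand() * 4) & 3]; } while (nb == base);
          b = nb;
          ++sub;
        }
        out.push_back(b);
        ++used;
      }
      if (!hit_cap) {
        del += dels;
        used += dels;
        for (int t = 0; t < inss; ++t) {
          if (capped && (int)out.size() >= cap) { hit_cap = true; break; }
          char b = base;
          if (bg_ins) {
            const char* alt = "ACGT";
            b = alt[(int)(R::unif_rand() * 4) & 3];
          }
          out.push_back(b);
          ++ins;
        }
      }
      i += L;
    }

    out_seq[r] = out;
    n_sub[r] = sub; n_ins[r] = ins; n_del[r] = del; src_used[r] = used;
  }
  return List::create(_["sequence"] = out_seq, _["n_sub"] = n_sub,
                      _["n_ins"] = n_ins, _["n_del"] = n_del,
                      _["src_used"] = src_used);
}

// ---------------------------------------------------------------------------
// minimizer index
// ---------------------------------------------------------------------------

struct MinHit { uint32_t read; uint8_t ori; uint16_t pos; };

static void minimizers(const std::string& s, int k, int w,
                       std::vector<std::pair<uint64_t, int> >& out) {
  int n = (int)s.size();
  out.clear();
  if (n < k) return;
  int nk = n - k + 1;
  std::vector<uint64_t> h((size_t)nk);
  uint64_t kmer = 0;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; kmer = 0; }
    else { kmer = ((kmer << 2) | (uint64_t)c) & mask; ++valid; }
    if (i >= k - 1) h[i - k + 1] = (valid >= k) ? mix64(kmer) : ~0ULL;
  }
  int last = -1;
  for (int i = 0; i + w - 1 < nk; ++i) {
    int best = i;
    for (int j = i + 1; j < i + w; ++j) if (h[j] < h[best]) best = j;
    if (best != last && h[best] != ~0ULL) {
      out.push_back(std::make_pair(h[best], best));
      last = best;
    }
  }
}

struct AlnCounts { long match, mismatch, ins, del; };
static AlnCounts banded_nw(const std::string& a, int as, int alen,
                           const std::string& b, int bs, int blen,
                           int extra_band);

// Hamming comparison with up to two single-base "diagonal repairs" (to
// tolerate an isolated indel inside an overlap).  Compares a[apos..] vs
// b[bpos..] over len columns; returns mismatch count and net shift applied
// to b at the far end.  mm capped at cap (early abandon).
static bool compare_repair(const std::string& a, int apos,
                           const std::string& b, int bpos, int len,
                           int cap, int& mm_out, int& shift_out,
                           int* first_repair = 0) {
  int mm = 0, shift = 0, repairs = 0;
  if (first_repair) *first_repair = len;
  int j = 0;
  while (j < len) {
    int ai = apos + j, bi = bpos + j + shift;
    if (ai >= (int)a.size() || bi >= (int)b.size() || bi < 0) break;
    if (a[ai] == b[bi]) { ++j; continue; }
    // mismatch: if a run of mismatches starts here, try a +/-1 shift repair
    int run = 0;
    while (j + run < len && apos + j + run < (int)a.size() &&
           bpos + j + run + shift < (int)b.size() &&
           a[apos + j + run] != b[bpos + j + run + shift]) ++run;
    if (run >= 4 && repairs < 2) {
      for (int d : { +1, -1 }) {
        int ok = 0;
        for (int t = 0; t < 8 && j + t < len; ++t) {
          int ai2 = apos + j + t, bi2 = bpos + j + t + shift + d;
          if (ai2 < (int)a.size() && bi2 >= 0 && bi2 < (int)b.size() &&
              a[ai2] == b[bi2]) ++ok;
        }
        if (ok >= 6) {
          if (first_repair && repairs == 0) *first_repair = j;
          shift += d; ++repairs; ++mm; run = 0; break;
        }
      }
      if (run == 0) { ++j; if (mm > cap) { mm_out = mm; shift_out = shift; return false; } continue; }
    }
    ++mm; ++j;
    if (mm > cap) { mm_out = mm; shift_out = shift; return false; }
  }
  mm_out = mm; shift_out = shift;
  return true;
}

// ---------------------------------------------------------------------------
// greedy overlap assembler (seed-and-extend contig building)
// ---------------------------------------------------------------------------

struct LayoutEntry { uint32_t read; uint8_t ori; int offset; int vote_lo, vote_hi; };

struct ExtCand {
  uint32_t read; uint8_t ori; int offset;
  int ovl; int mm; int shift; int first_repair;
  double score; bool contained;
};

// [[Rcpp::export]]
List cpp_greedy_assemble(CharacterVector seqs_in, int min_overlap,
                         double min_identity, int seed_k, int seed_w,
                         int branch_margin) {
  int n = seqs_in.size();
  std::vector<std::string> fwd((size_t)n), rev((size_t)n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(seqs_in[i]);
    rev[i] = revcomp(fwd[i]);
  }

  // minimizer index over both orientations of every read
  std::unordered_map<uint64_t, std::vector<MinHit> > index;
  index.reserve((size_t)n * 64);
  {
    std::vector<std::pair<uint64_t, int> > mins;
    for (int r = 0; r < n; ++r) {
      for (int o = 0; o < 2; ++o) {
        const std::string& s = o ? rev[r] : fwd[r];
        minimizers(s, seed_k, seed_w, mins);
        for (size_t t = 0; t < mins.size(); ++t) {
          MinHit h; h.read = (uint32_t)r; h.ori = (uint8_t)o;
          h.pos = (uint16_t)std::min(mins[t].second, 65535);
          index[mins[t].first].push_back(h);
        }
      }
    }
  }
  // adaptive repeat masking: drop buckets far above the median occupancy
  {
    // entry-weighted median bucket size: the occupancy of the bucket a
    // random seed falls in, robust to the mass of read-boundary minimizers
    std::vector<long> hist;
    long total = 0;
    for (std::unordered_map<uint64_t, std::vector<MinHit> >::iterator it = index.begin();
         it != index.end(); ++it) {
      size_t s = it->second.size();
      if (hist.size() <= s) hist.resize(s + 1, 0);
      hist[s] += (long)s;
      total += (long)s;
    }
    int maxocc = 1 << 30;
    if (total > 0) {
      long cum = 0;
      int wmed = 1;
      for (size_t s = 1; s < hist.size(); ++s) {
        cum += hist[s];
        if (cum * 2 >= total) { wmed = (int)s; break; }
      }
      maxocc = std::max(32, 6 * wmed);
    }
    for (std::unordered_map<uint64_t, std::vector<MinHit> >::iterator it = index.begin();
         it != index.end(); ++it)
      if ((int)it->second.size() > maxocc) it->second.clear();
  }

  std::vector<char> used((size_t)n, 0);
  // process order: longest first, then input order
  std::vector<int> order((size_t)n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (fwd[a].size() != fwd[b].size()) return fwd[a].size() > fwd[b].size();
    return a < b;
  });

  std::vector<std::string> contigs;
  std::vector<std::vector<LayoutEntry> > layouts;
  std::vector<std::pair<uint64_t, int> > wmins;
  const int WINDOW = 600;

  for (size_t oi = 0; oi < order.size(); ++oi) {
    int seed = order[oi];
    if (used[seed]) continue;
    used[seed] = 1;
    std::string contig = fwd[seed];
    std::vector<LayoutEntry> layout;
    std::vector<uint16_t> vcounts;  // 4 x contig-length running vote counts
    auto add_votes = [&](const LayoutEntry& e) {
      const std::string& rs = e.ori ? rev[e.read] : fwd[e.read];
      if (vcounts.size() < (size_t)contig.size() * 4)
        vcounts.resize((size_t)contig.size() * 4, 0);
      int jlo = std::max(0, e.vote_lo);
      int jhi = std::min((int)rs.size(), e.vote_hi);
      for (int j = jlo; j < jhi; ++j) {
        int p = e.offset + j;
        if (p < 0 || p >= (int)contig.size()) continue;
        int c = base_code(rs[j]);
        if (c >= 0 && vcounts[(size_t)p * 4 + c] < 65535)
          ++vcounts[(size_t)p * 4 + c];
      }
    };
    auto rebuild_votes = [&]() {
      vcounts.assign((size_t)contig.size() * 4, 0);
      for (size_t li = 0; li < layout.size(); ++li) add_votes(layout[li]);
    };
    auto polish_window = [&](int from) {
      if (vcounts.size() < (size_t)contig.size() * 4)
        vcounts.resize((size_t)contig.size() * 4, 0);
      int clen = (int)contig.size();
      for (int p = std::max(0, from); p < clen; ++p) {
        int bc = -1, bcount = 0, tot = 0;
        for (int c = 0; c < 4; ++c) {
          int v = vcounts[(size_t)p * 4 + c];
          tot += v;
          if (v > bcount) { bcount = v; bc = c; }
        }
        // overwrite only on a strict majority; ties keep the current base
        if (bcount * 2 > tot && bcount > 0) contig[p] = "ACGT"[bc];
      }
    };
    { LayoutEntry e; e.read = (uint32_t)seed; e.ori = 0; e.offset = 0;
      e.vote_lo = 0; e.vote_hi = (int)fwd[seed].size(); layout.push_back(e);
      add_votes(e); }

    for (int pass = 0; pass < 2; ++pass) {
      // extend the right end until it stalls
      for (;;) {
        int clen = (int)contig.size();
        int wstart = std::max(0, clen - WINDOW);
        minimizers(contig.substr(wstart), seed_k, seed_w, wmins);
        // vote per (read, ori, exact diagonal)
        std::unordered_map<uint64_t, int> vote;
        for (size_t t = 0; t < wmins.size(); ++t) {
          std::unordered_map<uint64_t, std::vector<MinHit> >::const_iterator it =
            index.find(wmins[t].first);
          if (it == index.end()) continue;
          const std::vector<MinHit>& hits = it->second;
          for (size_t hh = 0; hh < hits.size(); ++hh) {
            if (used[hits[hh].read]) continue;
            int diag = wstart + wmins[t].second - (int)hits[hh].pos;
            if (diag < 0) continue; // read would start before contig start
            int rel = diag - wstart + 2048;  // window-relative, fits 13 bits
            if (rel < 0 || rel > 8191) continue;
            uint64_t key = ((uint64_t)hits[hh].read << 14) |
                           ((uint64_t)hits[hh].ori << 13) |
                           (uint64_t)rel;
            ++vote[key];
          }
        }
        // keep the two best-supported diagonals per (read, ori): inside a
        // repeat the top-voted diagonal can belong to the wrong copy
        struct DiagPair {
          int v1, d1, v2, d2;
          DiagPair() : v1(0), d1(0), v2(0), d2(0) {}
        };
        std::unordered_map<uint64_t, DiagPair> best_diag;
        for (std::unordered_map<uint64_t, int>::iterator it = vote.begin();
             it != vote.end(); ++it) {
          uint64_t rk = it->first >> 13;
          int diag = (int)(it->first & 0x1fff) - 2048 + wstart;
          DiagPair& dp = best_diag[rk];
          if (it->second > dp.v1 ||
              (it->second == dp.v1 && diag < dp.d1)) {
            dp.v2 = dp.v1; dp.d2 = dp.d1;
            dp.v1 = it->second; dp.d1 = diag;
          } else if (it->second > dp.v2 ||
                     (it->second == dp.v2 && diag < dp.d2)) {
            dp.v2 = it->second; dp.d2 = diag;
          }
        }
        // collect candidates (best verifying diagonal of up to two)
        std::vector<ExtCand> cands;
        for (std::unordered_map<uint64_t, DiagPair>::iterator it =
               best_diag.begin(); it != best_diag.end(); ++it) {
          if (it->second.v1 < 2) continue;
          uint32_t r = (uint32_t)(it->first >> 1);
          uint8_t o = (uint8_t)(it->first & 1);
          int diag = it->second.d1;
          const std::string& rs = o ? rev[r] : fwd[r];
          int rlen = (int)rs.size();
          int ovl = 0, mm = 0, shift = 0, fr = 0;
          double ident = -1.0;
          int try_diags[2] = { diag, it->second.v2 >= 2 ? it->second.d2 : -1 };
          for (int td = 0; td < 2; ++td) {
            int dg = try_diags[td];
            if (dg < 0 || (td == 1 && dg == try_diags[0])) continue;
            int ov = std::min(clen - dg, rlen);
            if (ov < min_overlap) continue;
            int cap = (int)((1.0 - min_identity) * ov) + 1;
            int m2 = 0, sh2 = 0, fr2 = ov;
            bool ok = compare_repair(contig, dg, rs, 0, ov, cap, m2, sh2, &fr2);
            double id2 = ok ? 1.0 - (double)m2 / (double)ov : 0.0;
            if (!ok || id2 < min_identity) {
              // slow path: periodic sequence or a misvoted diagonal can
              // fail the repair heuristic though a near-exact match exists
              AlnCounts c = banded_nw(contig, dg, ov, rs, 0, ov, 8);
              long cols = c.match + c.mismatch + c.ins + c.del;
              id2 = cols > 0 ? (double)c.match / (double)cols : 0.0;
              if (id2 < min_identity) continue;
              m2 = (int)(c.mismatch + c.ins + c.del);
              sh2 = (int)(c.del - c.ins);
              fr2 = 0;  // rescued alignment: columns unsafe for votes
            }
            if (id2 > ident) {
              ident = id2; diag = dg; ovl = ov; mm = m2; shift = sh2; fr = fr2;
            }
          }
          if (ident < min_identity) continue;
          ExtCand c;
          c.read = r; c.ori = o; c.offset = diag; c.ovl = ovl; c.mm = mm;
          c.shift = shift; c.first_repair = (shift == 0) ? rlen : fr;
          c.score = (double)ovl * ident;
          c.contained = (diag + rlen + shift <= clen);
          cands.push_back(c);
        }
        if (cands.empty()) break;
        // shift-free overlaps first: an extender whose overlap needed an
        // indel repair would put a frameshift into the contig backbone
        std::sort(cands.begin(), cands.end(), [](const ExtCand& a, const ExtCand& b) {
          bool az = (a.shift == 0), bz = (b.shift == 0);
          if (az != bz) return az;
          if (a.score != b.score) return a.score > b.score;
          if (a.read != b.read) return a.read < b.read;
          return a.ori < b.ori;
        });
        // place contained reads into the layout
        ExtCand best; bool have_best = false;
        std::vector<const ExtCand*> rivals;
        for (size_t ci = 0; ci < cands.size(); ++ci) {
          if (cands[ci].contained) continue;
          if (!have_best) { best = cands[ci]; have_best = true; }
          else if (cands[ci].ovl >= best.ovl - branch_margin &&
                   cands[ci].shift == 0)
            rivals.push_back(&cands[ci]);
        }
        for (size_t ci = 0; ci < cands.size(); ++ci) {
          if (!cands[ci].contained) continue;
          used[cands[ci].read] = 1;
          LayoutEntry e; e.read = cands[ci].read; e.ori = cands[ci].ori;
          e.offset = cands[ci].offset;
          e.vote_lo = 0; e.vote_hi = cands[ci].first_repair;
          layout.push_back(e);
          add_votes(e);
        }
        if (!have_best) break;
        // branch check: extension stops only when a substantial fraction of
        // the near-best rivals imply a conflicting continuation (a repeat
        // boundary); a lone discordant read does not break the contig, so
        // the rule does not fire more often just because depth is higher
        int checked = 0, conflicted = 0;
        const std::string& bs = best.ori ? rev[best.read] : fwd[best.read];
        for (size_t ri = 0; ri < rivals.size(); ++ri) {
          const ExtCand* rv = rivals[ri];
          const std::string& vs = rv->ori ? rev[rv->read] : fwd[rv->read];
          int m = std::min((int)bs.size() - best.ovl, (int)vs.size() - rv->ovl);
          m = std::min(m, 200);
          if (m < 20) continue;
          int mm = 0, shift = 0;
          compare_repair(bs, best.ovl, vs, rv->ovl, m, m, mm, shift);
          ++checked;
          if ((double)mm > 0.25 * (double)m) ++conflicted;
        }
        bool conflict = conflicted >= 1 &&
          (double)conflicted >= 0.3 * (double)checked;
        if (conflict) break;
        // append the best extender
        used[best.read] = 1;
        LayoutEntry e; e.read = best.read; e.ori = best.ori; e.offset = best.offset;
        e.vote_lo = 0;
        e.vote_hi = (int)(best.ori ? rev[best.read] : fwd[best.read]).size();
        layout.push_back(e);
        contig += bs.substr(std::min((int)bs.size(),
                                     best.ovl + (best.shift > 0 ? best.shift : 0)));
        add_votes(e);
        polish_window((int)contig.size() - (int)bs.size() - 50);
      }
      if (pass == 0) {
        // flip and extend the other end
        int clen = (int)contig.size();
        contig = revcomp(contig);
        for (size_t li = 0; li < layout.size(); ++li) {
          int rlen = (int)fwd[layout[li].read].size();
          layout[li].offset = clen - layout[li].offset - rlen;
          layout[li].ori = 1 - layout[li].ori;
          int lo = layout[li].vote_lo, hi = layout[li].vote_hi;
          layout[li].vote_lo = rlen - hi; layout[li].vote_hi = rlen - lo;
        }
        rebuild_votes();
        polish_window((int)contig.size() - 700);
      }
    }
    // flip back so the seed read keeps its input orientation
    {
      int clen = (int)contig.size();
      contig = revcomp(contig);
      for (size_t li = 0; li < layout.size(); ++li) {
        int rlen = (int)fwd[layout[li].read].size();
        layout[li].offset = clen - layout[li].offset - rlen;
        layout[li].ori = 1 - layout[li].ori;
        int lo = layout[li].vote_lo, hi = layout[li].vote_hi;
        layout[li].vote_lo = rlen - hi; layout[li].vote_hi = rlen - lo;
      }
    }
    // consensus by per-column majority vote
    {
      int clen = (int)contig.size();
      std::vector<uint16_t> counts((size_t)clen * 4, 0);
      for (size_t li = 0; li < layout.size(); ++li) {
        const std::string& rs = layout[li].ori ? rev[layout[li].read] : fwd[layout[li].read];
        int off = layout[li].offset;
        int jlo = std::max(0, layout[li].vote_lo);
        int jhi = std::min((int)rs.size(), layout[li].vote_hi);
        for (int j = jlo; j < jhi; ++j) {
          int p = off + j;
          if (p < 0 || p >= clen) continue;
          int c = base_code(rs[j]);
          if (c >= 0 && counts[(size_t)p * 4 + c] < 65535) ++counts[(size_t)p * 4 + c];
        }
      }
      for (int p = 0; p < clen; ++p) {
        int bc = 0, bcount = -1, tot = 0;
        for (int c = 0; c < 4; ++c) {
          int v = counts[(size_t)p * 4 + c];
          tot += v;
          if (v > bcount) { bcount = v; bc = c; }
        }
        if (bcount > 0 && bcount * 2 > tot) contig[p] = "ACGT"[bc];
      }
    }
    contigs.push_back(contig);
    layouts.push_back(layout);
  }

  // drop contigs whose bases are (nearly) fully covered by matches to
  // longer contigs at >= min_identity; piecewise coverage handles reads
  // spanning the circular-closure junction of a rotated contig
  std::vector<int> corder((size_t)contigs.size());
  for (size_t i = 0; i < corder.size(); ++i) corder[i] = (int)i;
  std::stable_sort(corder.begin(), corder.end(), [&](int a, int b) {
    if (contigs[a].size() != contigs[b].size()) return contigs[a].size() > contigs[b].size();
    return contigs[a] < contigs[b];
  });
  std::vector<char> keep(contigs.size(), 1);
  {
    std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > cidx; // hash -> (contig, pos)
    std::vector<std::pair<uint64_t, int> > mins;
    for (size_t ci = 0; ci < corder.size(); ++ci) {
      int c = corder[ci];
      const std::string& s = contigs[c];
      int len = (int)s.size();
      bool dropped = false;
      if (ci > 0) {
        std::vector<char> cov((size_t)len, 0);
        for (int o = 0; o < 2; ++o) {
          std::string q = o ? revcomp(s) : s;
          minimizers(q, seed_k, 9, mins);
          std::unordered_map<uint64_t, int> vote;
          for (size_t t = 0; t < mins.size(); ++t) {
            std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::iterator it =
              cidx.find(mins[t].first);
            if (it == cidx.end()) continue;
            for (size_t hh = 0; hh < it->second.size(); ++hh) {
              int tc = it->second[hh].first;
              int diag = it->second[hh].second - mins[t].second;
              uint64_t key = ((uint64_t)tc << 24) |
                             (uint64_t)((diag + 2000000) & 0xffffff);
              ++vote[key];
            }
          }
          for (std::unordered_map<uint64_t, int>::iterator it = vote.begin();
               it != vote.end(); ++it) {
            if (it->second < 2) continue;
            int tc = (int)(it->first >> 24);
            int diag = (int)(it->first & 0xffffff) - 2000000;
            const std::string& ts = contigs[tc];
            // overlap of q with ts on this diagonal
            int q0 = std::max(0, -diag);
            int q1 = std::min(len, (int)ts.size() - diag);
            if (q1 - q0 < 30) continue;
            int seg = q1 - q0;
            int cap = (int)((1.0 - min_identity) * seg) + 2;
            int mm = 0, shift = 0;
            if (!compare_repair(ts, diag + q0, q, q0, seg, cap, mm, shift))
              continue;
            if (1.0 - (double)mm / seg < min_identity) continue;
            for (int p = q0; p < q1; ++p) {
              int qp = o ? len - 1 - p : p;
              cov[qp] = 1;
            }
          }
        }
        int covered = 0;
        for (int p = 0; p < len; ++p) covered += cov[p];
        if (covered >= (int)(0.95 * len)) dropped = true;
      }
      if (dropped) { keep[c] = 0; continue; }
      minimizers(s, seed_k, 19, mins);
      for (size_t t = 0; t < mins.size(); ++t)
        cidx[mins[t].first].push_back(std::make_pair(c, mins[t].second));
    }
  }

  std::vector<int> final_ids;
  for (size_t i = 0; i < corder.size(); ++i)
    if (keep[corder[i]]) final_ids.push_back(corder[i]);

  CharacterVector out(final_ids.size());
  IntegerVector out_nreads(final_ids.size());
  for (size_t i = 0; i < final_ids.size(); ++i) {
    out[i] = contigs[final_ids[i]];
    out_nreads[i] = (int)layouts[final_ids[i]].size();
  }
  return List::create(_["contigs"] = out, _["n_reads"] = out_nreads);
}

// ---------------------------------------------------------------------------
// banded global alignment with unit costs; returns column counts
// ---------------------------------------------------------------------------

// global alignment of ref segment a vs query segment b, band around the
// length-difference diagonal.  ins = base in b absent from a, del = base of
// a absent from b.  Guarantees match + mismatch + del == len(a).
static AlnCounts banded_nw(const std::string& a, int as, int alen,
                           const std::string& b, int bs, int blen,
                           int extra_band) {
  AlnCounts out; out.match = 0; out.mismatch = 0; out.ins = 0; out.del = 0;
  if (alen == 0) { out.ins = blen; return out; }
  if (blen == 0) { out.del = alen; return out; }
  int band = std::abs(alen - blen) + extra_band;
  int width = 2 * band + 1;
  const int INF = 1 << 28;
  std::vector<int> dp((size_t)(alen + 1) * width, INF);
  std::vector<int8_t> tb((size_t)(alen + 1) * width, 0); // 0 diag, 1 up(del), 2 left(ins)
  auto idx = [&](int i, int j) { return (size_t)i * width + (j - i + band); };
  auto inband = [&](int i, int j) { return j >= 0 && j <= blen && (j - i) >= -band && (j - i) <= band; };
  dp[idx(0, 0)] = 0;
  for (int j = 1; j <= blen && inband(0, j); ++j) { dp[idx(0, j)] = j; tb[idx(0, j)] = 2; }
  for (int i = 1; i <= alen; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(blen, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int best = INF; int8_t dir = 0;
      if (j > 0 && inband(i - 1, j - 1)) {
        int c = dp[idx(i - 1, j - 1)] + (a[as + i - 1] == b[bs + j - 1] ? 0 : 1);
        if (c < best) { best = c; dir = 0; }
      }
      if (inband(i - 1, j)) {
        int c = dp[idx(i - 1, j)] + 1;
        if (c < best) { best = c; dir = 1; }
      }
      if (j > 0 && inband(i, j - 1)) {
        int c = dp[idx(i, j - 1)] + 1;
        if (c < best) { best = c; dir = 2; }
      }
      dp[idx(i, j)] = best; tb[idx(i, j)] = dir;
    }
  }
  int i = alen, j = blen;
  while (i > 0 || j > 0) {
    int8_t dir = tb[idx(i, j)];
    if (i > 0 && j > 0 && dir == 0) {
      if (a[as + i - 1] == b[bs + j - 1]) ++out.match; else ++out.mismatch;
      --i; --j;
    } else if (i > 0 && dir == 1) { ++out.del; --i; }
    else { ++out.ins; --j; }
  }
  return out;
}

// End extension by banded semi-global alignment: the query tail from qp
// (moving dir = +1/-1) is aligned against the reference with the far
// reference end free; only the score-maximising prefix of the tail is
// kept so unrelated tails (e.g. chimeric junctions) do not count.
// Returns exact counts and the reference/query columns consumed.
static void tail_align(const std::string& ref, const std::string& qry,
                       int rp, int qp, int dir,
                       long& match, long& mismatch, long& ins, long& del,
                       int& radv, int& qadv) {
  match = mismatch = ins = del = 0; radv = qadv = 0;
  int R = (int)ref.size(), Q = (int)qry.size();
  int qlen = dir > 0 ? Q - qp : qp + 1;
  if (dir > 0) { if (qp >= Q || rp >= R) return; }
  else { if (qp < 0 || rp < 0) return; }
  qlen = dir > 0 ? Q - qp : qp + 1;
  if (qlen <= 0) return;
  if (qlen > 4000) qlen = 4000;  // cap runaway tails
  const int band = 8;
  int rlen = std::min(dir > 0 ? R - rp : rp + 1, qlen + band);
  if (rlen <= 0) return;
  auto rc_at = [&](int j) { return ref[rp + dir * j]; };
  auto qc_at = [&](int i) { return qry[qp + dir * i]; };
  const int INF = 1 << 28;
  int width = 2 * band + 1;
  std::vector<int> dp((size_t)(qlen + 1) * width, INF);
  std::vector<int8_t> tb((size_t)(qlen + 1) * width, 0);
  auto idx = [&](int i, int j) { return (size_t)i * width + (j - i + band); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= rlen && (j - i) >= -band && (j - i) <= band;
  };
  dp[idx(0, 0)] = 0;
  for (int j = 1; j <= rlen && inband(0, j); ++j) {
    dp[idx(0, j)] = j; tb[idx(0, j)] = 2;  // ref consumed, query not: del
  }
  for (int i = 1; i <= qlen; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(rlen, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int best = INF; int8_t d = 0;
      if (j > 0 && inband(i - 1, j - 1)) {
        int c = dp[idx(i - 1, j - 1)] + (qc_at(i - 1) == rc_at(j - 1) ? 0 : 1);
        if (c < best) { best = c; d = 0; }
      }
      if (inband(i - 1, j)) {  // query base unmatched: insertion
        int c = dp[idx(i - 1, j)] + 1;
        if (c < best) { best = c; d = 1; }
      }
      if (j > 0 && inband(i, j - 1)) {  // ref base skipped: deletion
        int c = dp[idx(i, j - 1)] + 1;
        if (c < best) { best = c; d = 2; }
      }
      dp[idx(i, j)] = best; tb[idx(i, j)] = d;
    }
  }
  // free reference end: best cell in the last query row
  int jbest = -1, cbest = INF;
  for (int j = std::max(0, qlen - band); j <= std::min(rlen, qlen + band); ++j) {
    if (inband(qlen, j) && dp[idx(qlen, j)] < cbest) {
      cbest = dp[idx(qlen, j)]; jbest = j;
    }
  }
  if (jbest < 0) return;
  // traceback into an op list (0 match, 1 mismatch, 2 ins, 3 del)
  std::vector<int8_t> ops;
  int i = qlen, j = jbest;
  while (i > 0 || j > 0) {
    int8_t d = tb[idx(i, j)];
    if (i > 0 && j > 0 && d == 0) {
      ops.push_back(qc_at(i - 1) == rc_at(j - 1) ? 0 : 1);
      --i; --j;
    } else if (i > 0 && d == 1) { ops.push_back(2); --i; }
    else { ops.push_back(3); --j; }
  }
  std::reverse(ops.begin(), ops.end());
  // keep the score-maximising prefix (match +1, error -2) so an
  // unrelated tail past a chimeric junction contributes nothing
  int cut = 0;
  long score = 0, best_score = 0;
  for (size_t t = 0; t < ops.size(); ++t) {
    score += (ops[t] == 0) ? 1 : -2;
    if (score > best_score) { best_score = score; cut = (int)t + 1; }
  }
  for (int t = 0; t < cut; ++t) {
    switch (ops[t]) {
    case 0: ++match; ++radv; ++qadv; break;
    case 1: ++mismatch; ++radv; ++qadv; break;
    case 2: ++ins; ++qadv; break;
    case 3: ++del; ++radv; break;
    }
  }
}

struct Anchor { int q, r; };

// Anchor-and-extend alignment of queries against one reference sequence.
// unique_only: use only k-mers unique in the reference (whole-assembly
// alignment); otherwise all k-mer hits up to max_occ (gene mapping).
// keep_overlaps: keep chains whose query span overlaps a better chain
// (needed to see duplicated loci).
// [[Rcpp::export]]
DataFrame cpp_align_blocks(CharacterVector queries, CharacterVector qnames,
                           std::string ref, int k, bool unique_only,
                           int max_occ, int min_anchors, bool keep_overlaps) {
  int R = (int)ref.size();
  // reference k-mer index
  std::unordered_map<uint64_t, std::vector<int> > ridx;
  ridx.reserve((size_t)std::max(1, R));
  for (int p = 0; p + k <= R; ++p) {
    uint64_t v;
    if (!encode_kmer(ref, p, k, v)) continue;
    std::vector<int>& vec = ridx[v];
    if ((int)vec.size() <= max_occ) vec.push_back(p);
  }

  std::vector<std::string> out_qid;
  std::vector<int> out_rs, out_re, out_qs, out_qe;
  std::vector<std::string> out_strand;
  std::vector<double> out_match, out_mismatch, out_ins, out_del;

  int nq = queries.size();
  for (int qi = 0; qi < nq; ++qi) {
    std::string qf = as<std::string>(queries[qi]);
    std::string qn = as<std::string>(qnames[qi]);
    struct Chain { std::vector<Anchor> a; int ori; };
    std::vector<Chain> chains;

    for (int o = 0; o < 2; ++o) {
      std::string q = o ? revcomp(qf) : qf;
      int Q = (int)q.size();
      std::vector<Anchor> anchors;
      for (int p = 0; p + k <= Q; ++p) {
        uint64_t v;
        if (!encode_kmer(q, p, k, v)) continue;
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = ridx.find(v);
        if (it == ridx.end()) continue;
        const std::vector<int>& vec = it->second;
        if ((int)vec.size() > max_occ) continue;
        if (unique_only && vec.size() != 1) continue;
        for (size_t h = 0; h < vec.size(); ++h) {
          Anchor a; a.q = p; a.r = vec[h]; anchors.push_back(a);
        }
      }
      std::sort(anchors.begin(), anchors.end(), [](const Anchor& x, const Anchor& y) {
        if (x.r != y.r) return x.r < y.r;
        return x.q < y.q;
      });
      // greedy co-linear chaining
      Chain cur; cur.ori = o;
      for (size_t ai = 0; ai < anchors.size(); ++ai) {
        if (cur.a.empty()) { cur.a.push_back(anchors[ai]); continue; }
        const Anchor& last = cur.a.back();
        int dq = anchors[ai].q - last.q, dr = anchors[ai].r - last.r;
        if (dq > 0 && dr > 0 && dq <= 5000 && dr <= 5000 && std::abs(dq - dr) <= 200) {
          cur.a.push_back(anchors[ai]);
        } else if (dq == 0 && dr == 0) {
          continue;
        } else {
          if ((int)cur.a.size() >= min_anchors) chains.push_back(cur);
          cur.a.clear(); cur.a.push_back(anchors[ai]);
        }
      }
      if ((int)cur.a.size() >= min_anchors) chains.push_back(cur);
    }

    // rank chains by anchor count, drop heavy query overlaps unless asked
    std::vector<int> chord(chains.size());
    for (size_t i = 0; i < chord.size(); ++i) chord[i] = (int)i;
    std::stable_sort(chord.begin(), chord.end(), [&](int x, int y) {
      return chains[x].a.size() > chains[y].a.size();
    });
    std::vector<std::pair<int, int> > taken; // query intervals on forward coords
    for (size_t ci = 0; ci < chord.size(); ++ci) {
      Chain& ch = chains[chord[ci]];
      int Q = (int)qf.size();
      int q0 = ch.a.front().q, q1 = ch.a.back().q + k;
      int fq0 = ch.ori ? Q - q1 : q0;
      int fq1 = ch.ori ? Q - q0 : q1;
      if (!keep_overlaps) {
        bool clash = false;
        for (size_t t = 0; t < taken.size(); ++t) {
          int lo = std::max(fq0, taken[t].first), hi = std::min(fq1, taken[t].second);
          if (hi - lo > (fq1 - fq0) / 2) { clash = true; break; }
        }
        if (clash) continue;
      }
      taken.push_back(std::make_pair(fq0, fq1));

      std::string q = ch.ori ? revcomp(qf) : qf;
      long m = 0, mm = 0, ins = 0, del = 0;
      int rs = ch.a.front().r, re = ch.a.front().r;
      int qs = ch.a.front().q, qe = ch.a.front().q;
      // walk anchors
      int prev_q = ch.a.front().q, prev_r = ch.a.front().r;
      m += k; // first anchor
      long cov_q = ch.a.front().q + k, cov_r = ch.a.front().r + k;
      for (size_t ai = 1; ai < ch.a.size(); ++ai) {
        int aq = ch.a[ai].q, ar = ch.a[ai].r;
        int dq = aq - prev_q, dr = ar - prev_r;
        if (dq == dr && dq <= k) {
          m += dq; // overlapping exact seeds with one offset: union is exact
        } else {
          // realign the whole stretch up to and including the new anchor;
          // both segment lengths are positive because anchors advance
          int gq0 = (int)cov_q, gr0 = (int)cov_r;
          int gqlen = (aq + k) - gq0, grlen = (ar + k) - gr0;
          AlnCounts c = banded_nw(ref, gr0, grlen, q, gq0, gqlen, 16);
          m += c.match; mm += c.mismatch; ins += c.ins; del += c.del;
        }
        prev_q = aq; prev_r = ar;
        cov_q = aq + k; cov_r = ar + k;
      }
      qe = prev_q + k; re = prev_r + k;
      // end extension by banded semi-global alignment
      {
        long em, emm, ei, ed; int radv, qadv;
        tail_align(ref, q, rs - 1, qs - 1, -1, em, emm, ei, ed, radv, qadv);
        m += em; mm += emm; ins += ei; del += ed; rs -= radv; qs -= qadv;
        tail_align(ref, q, re, qe, +1, em, emm, ei, ed, radv, qadv);
        m += em; mm += emm; ins += ei; del += ed; re += radv; qe += qadv;
      }
      int Qlen = (int)qf.size();
      int fqs = ch.ori ? Qlen - qe : qs;
      int fqe = ch.ori ? Qlen - qs : qe;
      out_qid.push_back(qn);
      out_rs.push_back(rs); out_re.push_back(re);
      out_qs.push_back(fqs); out_qe.push_back(fqe);
      out_strand.push_back(ch.ori ? "-" : "+");
      out_match.push_back((double)m); out_mismatch.push_back((double)mm);
      out_ins.push_back((double)ins); out_del.push_back((double)del);
    }
  }

  return DataFrame::create(
    _["qry_id"] = out_qid,
    _["ref_start"] = out_rs, _["ref_end"] = out_re,
    _["qry_start"] = out_qs, _["qry_end"] = out_qe,
    _["strand"] = out_strand,
    _["n_match"] = out_match, _["n_mismatch"] = out_mismatch,
    _["n_ins"] = out_ins, _["n_del"] = out_del,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// read placement on contigs (unique k-mer voting) for PE scaffolding
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_place_reads(CharacterVector reads, CharacterVector contigs,
                          int k, int min_votes) {
  int nc = contigs.size();
  std::vector<std::string> cs((size_t)nc);
  for (int i = 0; i < nc; ++i) cs[i] = as<std::string>(contigs[i]);
  // unique k-mer -> (contig, pos); duplicates masked
  std::unordered_map<uint64_t, int64_t> idx; // packed contig<<32|pos; -1 = dup
  for (int c = 0; c < nc; ++c) {
    const std::string& s = cs[c];
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t v;
      if (!encode_kmer(s, p, k, v)) continue;
      std::unordered_map<uint64_t, int64_t>::iterator it = idx.find(v);
      if (it == idx.end()) idx[v] = ((int64_t)c << 32) | (uint32_t)p;
      else it->second = -1;
    }
  }
  int nr = reads.size();
  IntegerVector out_contig(nr), out_pos(nr), out_votes(nr);
  CharacterVector out_strand(nr);
  for (int r = 0; r < nr; ++r) {
    std::string rf = as<std::string>(reads[r]);
    int bestc = -1, bestp = -1, bestv = 0; char bests = '+';
    for (int o = 0; o < 2; ++o) {
      std::string q = o ? revcomp(rf) : rf;
      std::unordered_map<int64_t, int> vote;
      for (int p = 0; p + k <= (int)q.size(); p += 4) {
        uint64_t v;
        if (!encode_kmer(q, p, k, v)) continue;
        std::unordered_map<uint64_t, int64_t>::const_iterator it = idx.find(v);
        if (it == idx.end() || it->second < 0) continue;
        int c = (int)(it->second >> 32);
        int cp = (int)(it->second & 0xffffffffLL);
        int64_t key = ((int64_t)c << 32) | (uint32_t)std::max(0, cp - p);
        ++vote[key];
      }
      for (std::unordered_map<int64_t, int>::iterator it = vote.begin();
           it != vote.end(); ++it) {
        int c = (int)(it->first >> 32);
        int pos = (int)(it->first & 0xffffffffLL);
        if (it->second > bestv ||
            (it->second == bestv && bestc >= 0 &&
             (c < bestc || (c == bestc && pos < bestp)))) {
          bestv = it->second; bestc = c; bestp = pos; bests = o ? '-' : '+';
        }
      }
    }
    if (bestv >= min_votes && bestc >= 0) {
      out_contig[r] = bestc + 1; out_pos[r] = bestp;
      out_votes[r] = bestv; out_strand[r] = std::string(1, bests);
    } else {
      out_contig[r] = NA_INTEGER; out_pos[r] = NA_INTEGER;
      out_votes[r] = bestv; out_strand[r] = NA_STRING;
    }
  }
  return DataFrame::create(_["contig"] = out_contig, _["pos"] = out_pos,
                           _["strand"] = out_strand, _["votes"] = out_votes,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// simplified de novo repeat finder: k-mer seeds + consensus extension
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_find_repeats(std::string g, int k, int min_len, int min_copies,
                           double min_ident, int max_occ) {
  int n = (int)g.size();
  std::string grc = revcomp(g);
  // canonical k-mer index: pos, ori (0 = genome kmer equals canonical form)
  std::unordered_map<uint64_t, std::vector<std::pair<int, uint8_t> > > idx;
  for (int p = 0; p + k <= n; ++p) {
    uint64_t vf, vr;
    if (!encode_kmer(g, p, k, vf)) continue;
    // rc of g[p..p+k) starts at grc[n-p-k]
    encode_kmer(grc, n - p - k, k, vr);
    uint64_t canon = std::min(vf, vr);
    uint8_t ori = (vf <= vr) ? 0 : 1;
    std::vector<std::pair<int, uint8_t> >& vec = idx[canon];
    if ((int)vec.size() <= max_occ) vec.push_back(std::make_pair(p, ori));
  }

  std::vector<char> covered((size_t)n, 0);
  std::vector<int> fam_id_out, start_out, end_out;
  std::vector<std::string> strand_out;
  int fam_counter = 0;

  struct Copy {
    int pos; int ori; bool alive; int lo, hi;
    uint32_t win;   // bitmask of the last 20 columns (1 = mismatch)
    int cols;
  };

  for (int p = 0; p + k <= n; ++p) {
    if (covered[p]) continue;
    uint64_t vf, vr;
    if (!encode_kmer(g, p, k, vf)) continue;
    encode_kmer(grc, n - p - k, k, vr);
    uint64_t canon = std::min(vf, vr);
    std::unordered_map<uint64_t, std::vector<std::pair<int, uint8_t> > >::iterator it =
      idx.find(canon);
    if (it == idx.end()) continue;
    if ((int)it->second.size() < min_copies ||
        (int)it->second.size() > max_occ) continue;
    // a k-mer straddling the repeat boundary can be shared by only a
    // subset of the copies (flank coincidence); prefer the densest
    // bucket within the next 2k positions as the family seed
    {
      int best_p = p, best_n = (int)it->second.size();
      for (int q = p + 1; q < p + 2 * k && q + k <= n; ++q) {
        if (covered[q]) break;
        uint64_t qf, qr2;
        if (!encode_kmer(g, q, k, qf)) continue;
        encode_kmer(grc, n - q - k, k, qr2);
        std::unordered_map<uint64_t, std::vector<std::pair<int, uint8_t> > >::iterator qi =
          idx.find(std::min(qf, qr2));
        if (qi == idx.end()) continue;
        int sz = (int)qi->second.size();
        if (sz > best_n && sz <= max_occ) { best_n = sz; best_p = q; }
      }
      if (best_p != p) {
        p = best_p;
        encode_kmer(g, p, k, vf);
        encode_kmer(grc, n - p - k, k, vr);
        canon = std::min(vf, vr);
        it = idx.find(canon);
      }
    }
    std::vector<std::pair<int, uint8_t> >& hits = it->second;
    if ((int)hits.size() < min_copies || (int)hits.size() > max_occ) continue;

    // orient copies relative to the copy at p
    uint8_t ori_p = 2;
    for (size_t h = 0; h < hits.size(); ++h)
      if (hits[h].first == p) { ori_p = hits[h].second; break; }
    if (ori_p == 2) continue;
    std::vector<Copy> copies;
    for (size_t h = 0; h < hits.size(); ++h) {
      if (covered[hits[h].first]) continue;
      Copy c; c.pos = hits[h].first;
      c.ori = (hits[h].second == ori_p) ? 0 : 1;
      c.alive = true; c.lo = 0; c.hi = k; c.win = 0; c.cols = 0;
      // drop copies overlapping an earlier accepted copy of this family
      bool clash = false;
      for (size_t cc = 0; cc < copies.size(); ++cc)
        if (std::abs(copies[cc].pos - c.pos) < k) clash = true;
      if (!clash) copies.push_back(c);
    }
    if ((int)copies.size() < min_copies) continue;

    // genome position of consensus offset t for copy c:
    //   ori 0:  pos + t          (base as-is)
    //   ori 1:  pos + k - 1 - t  (complement)
    auto base_at = [&](const Copy& c, int t) -> char {
      int gp = c.ori == 0 ? c.pos + t : c.pos + k - 1 - t;
      if (gp < 0 || gp >= n) return 0;
      return c.ori == 0 ? g[gp] : comp_base(g[gp]);
    };

    for (int dir = 0; dir < 2; ++dir) {
      int t = dir == 0 ? k : -1;
      for (;;) {
        int live = 0;
        int cnt[4] = {0, 0, 0, 0};
        for (size_t c = 0; c < copies.size(); ++c) {
          if (!copies[c].alive) continue;
          char b = base_at(copies[c], t);
          if (b == 0) { copies[c].alive = false; continue; }
          int bc = base_code(b);
          if (bc >= 0) { ++cnt[bc]; ++live; }
        }
        if (live < min_copies) break;
        int best = 0;
        for (int c2 = 1; c2 < 4; ++c2) if (cnt[c2] > cnt[best]) best = c2;
        char cons = "ACGT"[best];
        int win_cap = (int)((1.0 - min_ident) * 20.0) + 3;
        for (size_t c = 0; c < copies.size(); ++c) {
          if (!copies[c].alive) continue;
          char b = base_at(copies[c], t);
          ++copies[c].cols;
          copies[c].win = ((copies[c].win << 1) |
                           (b != cons ? 1u : 0u)) & 0xfffffu;
          if (copies[c].cols >= 10 &&
              (int)__builtin_popcount(copies[c].win) > win_cap) {
            // left the repeat: trim the trailing mismatch run back off
            int trim = 0;
            uint32_t w = copies[c].win;
            while ((w & 1u) && trim < 20) { w >>= 1; ++trim; }
            trim += win_cap;  // drop the tolerated mismatches too
            if (dir == 0) copies[c].hi = std::max(k, t + 1 - trim);
            else copies[c].lo = std::min(0, t + trim);
            copies[c].alive = false;
            continue;
          }
          if (dir == 0) copies[c].hi = t + 1; else copies[c].lo = t;
        }
        t += (dir == 0) ? 1 : -1;
        if (t > 50000 || t < -50000) break;
      }
      // reset mismatch accounting for the other direction, revive copies
      for (size_t c = 0; c < copies.size(); ++c) {
        copies[c].alive = true; copies[c].win = 0; copies[c].cols = 0;
      }
    }

    // materialise the family
    int nrep = 0;
    std::vector<std::pair<std::pair<int, int>, int> > intervals; // ((start,end), ori)
    for (size_t c = 0; c < copies.size(); ++c) {
      int lo = copies[c].lo, hi = copies[c].hi;
      if (hi - lo < min_len) continue;
      int gs, ge;
      if (copies[c].ori == 0) { gs = copies[c].pos + lo; ge = copies[c].pos + hi; }
      else { gs = copies[c].pos + k - hi; ge = copies[c].pos + k - lo; }
      gs = std::max(0, gs); ge = std::min(n, ge);
      if (ge - gs < min_len) continue;
      intervals.push_back(std::make_pair(std::make_pair(gs, ge), (int)copies[c].ori));
      ++nrep;
    }
    if (nrep < min_copies) continue;
    ++fam_counter;
    for (size_t iv = 0; iv < intervals.size(); ++iv) {
      fam_id_out.push_back(fam_counter);
      start_out.push_back(intervals[iv].first.first);
      end_out.push_back(intervals[iv].first.second);
      strand_out.push_back(intervals[iv].second == 0 ? "+" : "-");
      for (int q = intervals[iv].first.first; q < intervals[iv].first.second; ++q)
        covered[q] = 1;
    }
  }

  return DataFrame::create(_["family"] = fam_id_out, _["start"] = start_out,
                           _["end"] = end_out, _["strand"] = strand_out,
                           _["stringsAsFactors"] = false);
}
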