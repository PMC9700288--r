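// Seed-and-extend pairwise aligner: exact canonical k-mer seeds, collinear
// chaining per (target, strand), banded global DP between consecutive seed
// runs and banded semi-global extension at the ends.  Emits PAF-style
// records.  Deterministic for fixed inputs and parameters.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <map>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp_one(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = revcomp_one(as<std::string>(x[i]));
  }
  return out;
}

struct SeedHit {
  int32_t tid;
  int32_t pos;
  uint8_t fwd;  // 1 if the canonical k-mer equals the forward target k-mer
};

struct MiniIndex {
  int k = 15;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<SeedHit>> table;
};

// Enumerate canonical k-mers of `s`, calling f(pos, canon, is_forward)
// for every window free of non-ACGT characters.
template <typename F>
static void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t fw = 0, rc = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) {
      run = 0;
      fw = rc = 0;
      continue;
    }
    fw = ((fw << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      bool is_fwd = fw <= rc;
      f((int32_t)(i + 1 - k), is_fwd ? fw : rc, is_fwd);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k % 2 == 0 || k < 11 || k > 21)
    stop("k must be odd and between 11 and 21, got %d", k);
  MiniIndex* idx = new MiniIndex();
  idx->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(as<std::string>(seqs[i]));
  }
  for (size_t t = 0; t < idx->seqs.size(); ++t) {
    for_each_kmer(idx->seqs[t], k, [&](int32_t pos, uint64_t canon, bool fwd) {
      idx->table[canon].push_back(SeedHit{(int32_t)t, pos, (uint8_t)(fwd ? 1 : 0)});
    });
  }
  XPtr<MiniIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp) {
  XPtr<MiniIndex> idx(xp);
  std::vector<int> lens;
  for (auto& s : idx->seqs) lens.push_back((int)s.size());
  return List::create(_["k"] = idx->k,
                      _["n_targets"] = (int)idx->seqs.size(),
                      _["n_kmers"] = (double)idx->table.size(),
                      _["target_len"] = wrap(lens),
                      _["target_id"] = wrap(idx->names));
}

struct Anchor {
  int32_t q, t;
};

// One gap-filling banded global alignment between two short segments.
// Returns matches (M) and alignment columns; linear gap penalty.
struct SegAln {
  int matches = 0;
  int cols = 0;
};

static const int MATCH = 2, MISMATCH = -4, GAP = -3;
static const int NEG_INF = -1000000000;

// Banded global alignment of a[0..la) vs b[0..lb); band half-width bw
// around the (scaled) diagonal.  Tracks matches and diagonal steps along
// the best-scoring path (tie-break: diagonal > up(gap in b) > left).
static SegAln banded_global(const char* a, int la, const char* b, int lb, int bw) {
  SegAln out;
  if (la == 0 && lb == 0) return out;
  if (la == 0) { out.cols = lb; return out; }
  if (lb == 0) { out.cols = la; return out; }
  int band = std::max(bw, std::abs(la - lb) + bw);
  int w = 2 * band + 1;
  // cell (i, j) stored at row i, offset j - (i + off) + band where off = 0
  // diag mapping: center j = i * lb / la approximated by j = i + (lb - la) * i / la;
  // use simple j in [i - band + min(0, lb-la), i + band + max(0, lb-la)] via shift
  std::vector<int> sc_prev(w, NEG_INF), sc_cur(w, NEG_INF);
  std::vector<int> m_prev(w, 0), m_cur(w, 0);
  std::vector<int> d_prev(w, 0), d_cur(w, 0);
  auto center = [&](int i) { return (int)((long long)i * lb / la); };
  int c0 = center(0);
  for (int j = std::max(0, c0 - band); j <= std::min(lb, c0 + band); ++j) {
    int o = j - c0 + band;
    sc_prev[o] = GAP * j;
    m_prev[o] = 0;
    d_prev[o] = 0;
  }
  for (int i = 1; i <= la; ++i) {
    int ci = center(i), cp = center(i - 1);
    std::fill(sc_cur.begin(), sc_cur.end(), NEG_INF);
    int jlo = std::max(0, ci - band), jhi = std::min(lb, ci + band);
    for (int j = jlo; j <= jhi; ++j) {
      int o = j - ci + band;
      int best = NEG_INF, bm = 0, bd = 0;
      // diagonal
      if (j >= 1) {
        int op = (j - 1) - cp + band;
        if (op >= 0 && op < w && sc_prev[op] > NEG_INF) {
          bool eq = (a[i - 1] == b[j - 1]) && a[i - 1] != 'N';
          int s = sc_prev[op] + (eq ? MATCH : MISMATCH);
          if (s > best) { best = s; bm = m_prev[op] + (eq ? 1 : 0); bd = d_prev[op] + 1; }
        }
      }
      // up: gap in b (consume a)
      {
        int op = j - cp + band;
        if (op >= 0 && op < w && sc_prev[op] > NEG_INF) {
          int s = sc_prev[op] + GAP;
          if (s > best) { best = s; bm = m_prev[op]; bd = d_prev[op]; }
        }
      }
      // left: gap in a (consume b)
      if (j >= 1) {
        int ol = (j - 1) - ci + band;
        if (ol >= 0 && ol < w && sc_cur[ol] > NEG_INF) {
          int s = sc_cur[ol] + GAP;
          if (s > best) { best = s; bm = m_cur[ol]; bd = d_cur[ol]; }
        }
      }
      sc_cur[o] = best;
      m_cur[o] = bm;
      d_cur[o] = bd;
    }
    std::swap(sc_prev, sc_cur);
    std::swap(m_prev, m_cur);
    std::swap(d_prev, d_cur);
  }
  int cl = center(la);
  int o = lb - cl + band;
  if (o < 0 || o >= w || sc_prev[o] <= NEG_INF) {
    // band missed the corner (extreme length difference): count as all-gap
    out.matches = 0;
    out.cols = la + lb;
    return out;
  }
  out.matches = m_prev[o];
  out.cols = la + lb - d_prev[o];
  return out;
}

// Banded semi-global extension from (0,0) into a[0..la) x b[0..lb):
// best-scoring cell anywhere defines the extension end point.
struct ExtAln {
  int ai = 0, bj = 0;  // extension lengths consumed on a and b
  int matches = 0;
  int cols = 0;
};

static ExtAln banded_extend(const char* a, int la, const char* b, int lb, int bw) {
  ExtAln out;
  if (la == 0 || lb == 0) return out;
  int band = bw;
  int w = 2 * band + 1;
  std::vector<int> sc_prev(w, NEG_INF), sc_cur(w, NEG_INF);
  std::vector<int> m_prev(w, 0), m_cur(w, 0);
  std::vector<int> d_prev(w, 0), d_cur(w, 0);
  int best_score = 0, best_i = 0, best_j = 0, best_m = 0, best_d = 0;
  // center diagonal j = i
  for (int j = 0; j <= std::min(lb, band); ++j) {
    int o = j + band;  // i = 0, center 0
    sc_prev[o] = GAP * j;
  }
  for (int i = 1; i <= la; ++i) {
    std::fill(sc_cur.begin(), sc_cur.end(), NEG_INF);
    int jlo = std::max(0, i - band), jhi = std::min(lb, i + band);
    if (jlo > jhi) break;
    for (int j = jlo; j <= jhi; ++j) {
      int o = j - i + band;
      int best = NEG_INF, bm = 0, bd = 0;
      if (j >= 1) {
        int op = (j - 1) - (i - 1) + band;
        if (op >= 0 && op < w && sc_prev[op] > NEG_INF) {
          bool eq = (a[i - 1] == b[j - 1]) && a[i - 1] != 'N';
          int s = sc_prev[op] + (eq ? MATCH : MISMATCH);
          if (s > best) { best = s; bm = m_prev[op] + (eq ? 1 : 0); bd = d_prev[op] + 1; }
        }
      }
      {
        int op = j - (i - 1) + band;
        if (op >= 0 && op < w && sc_prev[op] > NEG_INF) {
          int s = sc_prev[op] + GAP;
          if (s > best) { best = s; bm = m_prev[op]; bd = d_prev[op]; }
        }
      }
      if (j >= 1) {
        int ol = (j - 1) - i + band;
        if (ol >= 0 && ol < w && sc_cur[ol] > NEG_INF) {
          int s = sc_cur[ol] + GAP;
          if (s > best) { best = s; bm = m_cur[ol]; bd = d_cur[ol]; }
        }
      }
      sc_cur[o] = best;
      m_cur[o] = bm;
      d_cur[o] = bd;
      if (best > best_score) {
        best_score = best;
        best_i = i; best_j = j; best_m = bm; best_d = bd;
      }
    }
    std::swap(sc_prev, sc_cur);
    std::swap(m_prev, m_cur);
    std::swap(d_prev, d_cur);
  }
  out.ai = best_i;
  out.bj = best_j;
  out.matches = best_m;
  out.cols = best_i + best_j - best_d;
  return out;
}

struct Chain {
  std::vector<Anchor> anchors;  // q ascending
  int tid = -1;
  bool minus = false;
  int score = 0;
};

struct PafRec {
  int q_start, q_end;
  bool minus;
  int tid;
  int t_start, t_end;
  int n_matches, block_len;
};

// Exact-match runs after collapsing co-diagonal overlapping anchors.
struct Run {
  int qs, qe, ts, te;
};

static std::vector<Run> chain_to_runs(const std::vector<Anchor>& ch, int k) {
  std::vector<Run> runs;
  for (const auto& a : ch) {
    if (!runs.empty()) {
      Run& r = runs.back();
      if ((long long)a.t - a.q == (long long)r.ts - r.qs && a.q <= r.qe) {
        r.qe = std::max(r.qe, a.q + k);
        r.te = r.ts + (r.qe - r.qs);
        continue;
      }
      if (a.q >= r.qe && a.t >= r.te) {
        runs.push_back(Run{a.q, a.q + k, a.t, a.t + k});
        continue;
      }
      continue;  // conflicting anchor, skip
    }
    runs.push_back(Run{a.q, a.q + k, a.t, a.t + k});
  }
  return runs;
}

// Align along a chain: exact runs + gap segments + end extensions.
static PafRec chain_align(const std::string& q, const std::string& t,
                          const std::vector<Anchor>& ch, int k, int band,
                          int max_ext) {
  std::vector<Run> runs = chain_to_runs(ch, k);
  PafRec rec;
  rec.n_matches = 0;
  rec.block_len = 0;
  for (size_t i = 0; i < runs.size(); ++i) {
    int len = runs[i].qe - runs[i].qs;
    rec.n_matches += len;
    rec.block_len += len;
    if (i > 0) {
      int qa = runs[i - 1].qe, qb = runs[i].qs;
      int ta = runs[i - 1].te, tb = runs[i].ts;
      SegAln seg = banded_global(q.data() + qa, qb - qa, t.data() + ta, tb - ta, band);
      rec.n_matches += seg.matches;
      rec.block_len += seg.cols;
    }
  }
  int qs = runs.front().qs, qe = runs.back().qe;
  int ts = runs.front().ts, te = runs.back().te;
  // suffix extension
  {
    int la = std::min((int)q.size() - qe, max_ext);
    int lb = std::min((int)t.size() - te, la + band);
    ExtAln e = banded_extend(q.data() + qe, la, t.data() + te, lb, band);
    qe += e.ai; te += e.bj;
    rec.n_matches += e.matches;
    rec.block_len += e.cols;
  }
  // prefix extension (on reversed strings)
  {
    int la = std::min(qs, max_ext);
    int lb = std::min(ts, la + band);
    std::string arv(q.begin() + (qs - la), q.begin() + qs);
    std::reverse(arv.begin(), arv.end());
    std::string brv(t.begin() + (ts - lb), t.begin() + ts);
    std::reverse(brv.begin(), brv.end());
    ExtAln e = banded_extend(arv.data(), la, brv.data(), lb, band);
    qs -= e.ai; ts -= e.bj;
    rec.n_matches += e.matches;
    rec.block_len += e.cols;
  }
  rec.q_start = qs;
  rec.q_end = qe;
  rec.t_start = ts;
  rec.t_end = te;
  return rec;
}

// Best chain among anchors of one (tid, strand) group.  Anchors sorted by
// (q, t).  Standard O(n^2) DP with a gap window; alive[] masks anchors
// whose forward-query position is already claimed by an emitted chain.
static Chain best_chain_group(const std::vector<Anchor>& anc,
                              const std::vector<char>& alive,
                              int max_gap, int band) {
  int n = (int)anc.size();
  std::vector<int> score(n, 0), pred(n, -1);
  int best = -1, best_score = 0;
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    score[i] = 1;
    for (int j = i - 1; j >= 0; --j) {
      if (anc[i].q - anc[j].q > max_gap) break;
      if (!alive[j]) continue;
      if (anc[j].q >= anc[i].q) continue;
      if (anc[j].t >= anc[i].t) continue;
      if (anc[i].t - anc[j].t > max_gap) continue;
      long long drift = (long long)(anc[i].t - anc[j].t) - (anc[i].q - anc[j].q);
      if (drift > band || drift < -band) continue;
      if (score[j] + 1 > score[i]) {
        score[i] = score[j] + 1;
        pred[i] = j;
      }
    }
    if (score[i] > best_score ||
        (score[i] == best_score && best >= 0 && anc[i].q < anc[best].q)) {
      best_score = score[i];
      best = i;
    }
  }
  Chain ch;
  if (best < 0) return ch;
  ch.score = best_score;
  for (int i = best; i >= 0; i = pred[i]) ch.anchors.push_back(anc[i]);
  std::reverse(ch.anchors.begin(), ch.anchors.end());
  return ch;
}

// [[Rcpp::export]]
DataFrame cpp_align(std::string query, SEXP xp, int max_occ, int min_chain_span,
                    int max_seed_gap, int band_width, int min_seeds,
                    int max_chains, int max_ext) {
  XPtr<MiniIndex> idx(xp);
  const int k = idx->k;

  std::vector<int> o_qs, o_qe, o_ts, o_te, o_nm, o_bl, o_tid;
  std::vector<bool> o_minus;

  int qlen = (int)query.size();
  if (qlen >= k) {
    std::string qrc = revcomp_one(query);
    // anchors grouped by (strand, tid); strand 0 = '+', 1 = '-'
    // '-' anchors use coordinates on the reverse-complemented query.
    std::map<std::pair<int, int>, std::vector<Anchor>> groups;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& qs = strand == 0 ? query : qrc;
      for_each_kmer(qs, k, [&](int32_t pos, uint64_t canon, bool fwd) {
        auto it = idx->table.find(canon);
        if (it == idx->table.end()) return;
        if ((int)it->second.size() > max_occ) return;
        for (const auto& h : it->second) {
          if ((h.fwd == 1) == fwd) {
            groups[{strand, h.tid}].push_back(Anchor{pos, h.pos});
          }
        }
      });
    }
    for (auto& g : groups) {
      std::sort(g.second.begin(), g.second.end(), [](const Anchor& a, const Anchor& b) {
        return a.q != b.q ? a.q < b.q : a.t < b.t;
      });
    }
    // Chains are extracted independently per (strand, target): after a
    // chain is emitted, only that group's anchors inside its query
    // interval are retired, so all-vs-all queries report every partner.
    for (auto& g : groups) {
      std::vector<char> alive(g.second.size(), 1);
      bool minus = g.first.first == 1;
      int tid = g.first.second;
      for (int iter = 0; iter < max_chains; ++iter) {
        Chain ch = best_chain_group(g.second, alive, max_seed_gap, band_width);
        if (ch.anchors.empty()) break;
        int span = ch.anchors.back().q + k - ch.anchors.front().q;
        if (span < min_chain_span || ch.score < min_seeds) break;
        const std::string& qs = minus ? qrc : query;
        PafRec rec = chain_align(qs, idx->seqs[tid], ch.anchors, k,
                                 band_width, max_ext);
        int fq_start = minus ? qlen - rec.q_end : rec.q_start;
        int fq_end = minus ? qlen - rec.q_start : rec.q_end;
        if (rec.block_len > 0 && rec.n_matches > 0) {
          o_qs.push_back(fq_start);
          o_qe.push_back(fq_end);
          o_ts.push_back(rec.t_start);
          o_te.push_back(rec.t_end);
          o_nm.push_back(rec.n_matches);
          o_bl.push_back(rec.block_len);
          o_tid.push_back(tid);
          o_minus.push_back(minus);
        }
        // retire this group's anchors inside the chain's query interval
        int cq_lo = ch.anchors.front().q, cq_hi = ch.anchors.back().q + k;
        for (size_t i = 0; i < g.second.size(); ++i) {
          if (!alive[i]) continue;
          int q0 = g.second[i].q;
          if (q0 + k > cq_lo && q0 < cq_hi) alive[i] = 0;
        }
      }
    }
  }

  int n = (int)o_qs.size();
  CharacterVector strand(n), target(n);
  IntegerVector tlen(n), qlen_v(n);
  for (int i = 0; i < n; ++i) {
    strand[i] = o_minus[i] ? "-" : "+";
    target[i] = idx->names[o_tid[i]];
    tlen[i] = (int)idx->seqs[o_tid[i]].size();
    qlen_v[i] = qlen;
  }
  DataFrame df = DataFrame::create(
      _["query_len"] = qlen_v, _["q_start"] = wrap(o_qs), _["q_end"] = wrap(o_qe),
      _["strand"] = strand, _["target_id"] = target, _["target_len"] = tlen,
      _["t_start"] = wrap(o_ts), _["t_end"] = wrap(o_te),
      _["n_matches"] = wrap(o_nm), _["block_len"] = wrap(o_bl),
      _["stringsAsFactors"] = false);
  return df;
}
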