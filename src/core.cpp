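#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

// Ungapped full-length matching of query sequences against a set of subject
// sequences (chromosomes or transcripts), on one or both strands, with a
// mismatch budget. Matching is seed-and-extend over a 7-mer positional index;
// for <=1 mismatch two disjoint 7-mer seeds cover every placement of a query
// of length >= 14 (pigeonhole). Shorter queries, or larger mismatch budgets,
// fall back to a window scan. N never matches anything.

static const int KSEED = 7;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// pack a k-mer starting at p; returns -1 if it contains a non-ACGT base
static inline long pack_kmer(const std::string &s, size_t p) {
  long v = 0;
  for (int j = 0; j < KSEED; ++j) {
    int b = base_code(s[p + j]);
    if (b < 0) return -1;
    v = (v << 2) | b;
  }
  return v;
}

struct SubjectIndex {
  // positions of every 7-mer, flattened: entry = (subject << 33) | (strand << 32) | pos
  std::vector<std::vector<uint64_t> > slots;
  const std::vector<std::string> *fwd;
  std::vector<std::string> rev; // reverse complements (built only if both_strands)
  bool both;
};

static void build_index(SubjectIndex &idx, const std::vector<std::string> &subjects,
                        bool both_strands) {
  idx.slots.assign(1L << (2 * KSEED), std::vector<uint64_t>());
  idx.fwd = &subjects;
  idx.both = both_strands;
  if (both_strands) {
    idx.rev.resize(subjects.size());
    for (size_t i = 0; i < subjects.size(); ++i) idx.rev[i] = revcomp(subjects[i]);
  }
  for (size_t si = 0; si < subjects.size(); ++si) {
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      const std::string &s = strand == 0 ? subjects[si] : idx.rev[si];
      if ((long)s.size() < KSEED) continue;
      for (size_t p = 0; p + KSEED <= s.size(); ++p) {
        long key = pack_kmer(s, p);
        if (key >= 0)
          idx.slots[key].push_back(((uint64_t)si << 33) | ((uint64_t)strand << 32) | p);
      }
    }
  }
}

// count mismatches of q against s[start..start+L), early exit above budget
static inline int count_mm(const std::string &q, const std::string &s, size_t start,
                           int budget) {
  int mm = 0;
  for (size_t j = 0; j < q.size(); ++j) {
    char a = q[j], b = s[start + j];
    if (a != b || a == 'N') {
      if (++mm > budget) return mm;
    }
  }
  return mm;
}

struct Hit { int subject; int strand; long start; int mm; };

static void verify_candidate(const std::string &q, const SubjectIndex &idx,
                             int subject, int strand, long start, int max_mismatch,
                             int min_match, std::vector<Hit> &out) {
  const std::string &s = strand == 0 ? (*idx.fwd)[subject] : idx.rev[subject];
  if (start < 0 || start + (long)q.size() > (long)s.size()) return;
  int mm = count_mm(q, s, start, max_mismatch);
  if (mm > max_mismatch) return;
  if ((int)q.size() - mm < min_match) return;
  Hit h; h.subject = subject; h.strand = strand; h.start = start; h.mm = mm;
  out.push_back(h);
}

static void find_hits_one(const std::string &q, const SubjectIndex &idx,
                          int max_mismatch, int min_match, std::vector<Hit> &out) {
  out.clear();
  int L = (int)q.size();
  if (L - max_mismatch < min_match || L < 1) return;
  bool indexable = (max_mismatch <= 1) && (L >= 2 * KSEED);
  if (indexable) {
    std::vector<int> offsets;
    offsets.push_back(0);
    if (max_mismatch == 1) offsets.push_back(KSEED);
    std::vector<uint64_t> cands;
    bool seed_ok = false;
    for (size_t oi = 0; oi < offsets.size(); ++oi) {
      long key = pack_kmer(q, offsets[oi]);
      if (key < 0) continue; // seed contains N; the other seed must cover
      seed_ok = true;
      const std::vector<uint64_t> &pos = idx.slots[key];
      for (size_t t = 0; t < pos.size(); ++t) {
        long p = (long)(pos[t] & 0xFFFFFFFFULL);
        uint64_t head = pos[t] >> 32; // (subject << 1) | strand
        cands.push_back((head << 32) | (uint64_t)(p - offsets[oi] + (1L << 30)));
      }
    }
    if (seed_ok || max_mismatch == 0) {
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (size_t t = 0; t < cands.size(); ++t) {
        long start = (long)(cands[t] & 0xFFFFFFFFULL) - (1L << 30);
        uint64_t head = cands[t] >> 32;
        verify_candidate(q, idx, (int)(head >> 1), (int)(head & 1), start,
                         max_mismatch, min_match, out);
      }
      return;
    }
    // both seeds contained N with a 1-mismatch budget: fall through to scan
  }
  // window scan fallback
  for (size_t si = 0; si < idx.fwd->size(); ++si) {
    for (int strand = 0; strand < (idx.both ? 2 : 1); ++strand) {
      const std::string &s = strand == 0 ? (*idx.fwd)[si] : idx.rev[si];
      if ((long)s.size() < L) continue;
      for (size_t p = 0; p + L <= s.size(); ++p) {
        verify_candidate(q, idx, (int)si, strand, (long)p, max_mismatch,
                         min_match, out);
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_find_hits")]]
List cpp_find_hits(CharacterVector queries, CharacterVector subject_seqs,
                   int min_match, int max_mismatch, int max_loci,
                   bool both_strands) {
  std::vector<std::string> subjects(subject_seqs.size());
  for (int i = 0; i < subject_seqs.size(); ++i)
    subjects[i] = as<std::string>(subject_seqs[i]);
  SubjectIndex idx;
  build_index(idx, subjects, both_strands);

  std::vector<int> o_query, o_subject, o_mm;
  std::vector<long> o_start;
  std::vector<int> o_strand;
  IntegerVector n_loci(queries.size());
  LogicalVector exceeds(queries.size());

  std::vector<Hit> hits;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    find_hits_one(q, idx, max_mismatch, min_match, hits);
    n_loci[qi] = (int)hits.size();
    if ((int)hits.size() > max_loci) { exceeds[qi] = true; continue; }
    exceeds[qi] = false;
    for (size_t h = 0; h < hits.size(); ++h) {
      long start = hits[h].start;
      int subj = hits[h].subject;
      if (hits[h].strand == 1) {
        // position on the reverse complement -> forward coordinates
        long len = (long)subjects[subj].size();
        start = len - (start + (long)q.size());
      }
      o_query.push_back(qi + 1);
      o_subject.push_back(subj + 1);
      o_start.push_back(start + 1); // 1-based
      o_strand.push_back(hits[h].strand);
      o_mm.push_back(hits[h].mm);
    }
  }
  return List::create(
    _["query"] = wrap(o_query), _["subject"] = wrap(o_subject),
    _["start"] = wrap(o_start), _["strand_code"] = wrap(o_strand),
    _["mismatches"] = wrap(o_mm), _["n_loci"] = n_loci,
    _["exceeds_max_loci"] = exceeds);
}

// 3' adapter trimming: leftmost occurrence of the adapter (or of an adapter
// prefix reaching the read end) with mismatch fraction <= max_error_rate over
// the overlapped bases, minimum overlap min_overlap. Returns the insert
// length per read (read length when no occurrence is found).
// [[Rcpp::export(name = ".cpp_trim_adapter")]]
IntegerVector cpp_trim_adapter(CharacterVector reads, std::string adapter,
                               double max_error_rate, int min_overlap) {
  int alen = (int)adapter.size();
  IntegerVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    int len = (int)s.size();
    int cut = len;
    for (int i = 0; i + min_overlap <= len; ++i) {
      int overlap = std::min(alen, len - i);
      int allowed = (int)std::floor(max_error_rate * overlap + 1e-9);
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < overlap; ++j) {
        if (s[i + j] != adapter[j]) {
          if (++mm > allowed) { ok = false; break; }
        }
      }
      if (ok) { cut = i; break; }
    }
    out[r] = cut;
  }
  return out;
}
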