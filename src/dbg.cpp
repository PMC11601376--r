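// De Bruijn graph core: canonical k-mer counting and unitig (maximal
// non-branching path) construction over the solid k-mer set. The graph is
// bidirected: every unitig represents itself and its reverse complement;
// links are emitted on oriented unitigs (orientation 0 = forward sequence as
// stored, 1 = reverse complement) and are symmetric by construction.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline bool acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// canonical form = lexicographic min of kmer and its reverse complement
static inline std::string canon(const std::string& s) {
  std::string rc = revcomp(s);
  return (rc < s) ? rc : s;
}

typedef std::unordered_map<std::string, int> KmerCount;

static void count_read(const std::string& seq, int k, KmerCount& counts) {
  int n = (int)seq.size();
  if (n < k) return;
  // track last invalid base so windows containing it are skipped
  int last_bad = -1;
  for (int i = 0; i < n; ++i) {
    if (!acgt(seq[i])) last_bad = i;
    int start = i - k + 1;
    if (start < 0 || last_bad >= start) continue;
    counts[canon(seq.substr(start, k))]++;
  }
}

struct OrientedRef { int id; int orient; };

// successors of an oriented kmer within the solid set
static int succ_count(const std::string& x, int k,
                      const std::unordered_set<std::string>& solid,
                      std::string* only = NULL) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  int n = 0;
  std::string y = x.substr(1) + "A";
  for (int i = 0; i < 4; ++i) {
    y[k - 1] = B[i];
    if (solid.count(canon(y))) {
      ++n;
      if (only) *only = y;
    }
  }
  return n;
}

static int pred_count(const std::string& x, int k,
                      const std::unordered_set<std::string>& solid,
                      std::string* only = NULL) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  int n = 0;
  std::string y = "A" + x.substr(0, k - 1);
  for (int i = 0; i < 4; ++i) {
    y[0] = B[i];
    if (solid.count(canon(y))) {
      ++n;
      if (only) *only = y;
    }
  }
  return n;
}

// [[Rcpp::export]]
List cpp_build_unitig_graph(CharacterVector reads, int k, int min_count) {
  if (k % 2 == 0) stop("k must be odd");
  KmerCount counts;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    count_read(s, k, counts);
  }
  // solid set, sorted for deterministic traversal order
  std::vector<std::string> kept;
  kept.reserve(counts.size());
  for (KmerCount::const_iterator it = counts.begin(); it != counts.end(); ++it)
    if (it->second >= min_count) kept.push_back(it->first);
  std::sort(kept.begin(), kept.end());
  std::unordered_set<std::string> solid(kept.begin(), kept.end());

  std::unordered_set<std::string> visited; // canonical kmers already in a unitig
  std::vector<std::string> useq;           // unitig forward sequences
  std::vector<double> ucov;                // mean kmer multiplicity
  std::vector<std::string> ufirst, ulast;  // first/last oriented kmer (forward)

  // a unitig starts at oriented kmer x when the chain cannot be extended
  // backwards unambiguously
  for (size_t i = 0; i < kept.size(); ++i) {
    const std::string& km = kept[i];
    if (visited.count(km)) continue;
    std::string rc = revcomp(km);
    const std::string* orients[2] = {&km, &rc};
    for (int o = 0; o < 2; ++o) {
      const std::string& x = *orients[o];
      std::string p;
      int np = pred_count(x, k, solid, &p);
      bool start = (np != 1);
      if (!start) {
        int nsp = succ_count(p, k, solid);
        start = (nsp != 1);
      }
      if (!start) continue;
      if (visited.count(km)) break;
      // walk forward
      std::string cur = x;
      std::string seq = x;
      double covsum = counts[canon(x)];
      int nk = 1;
      visited.insert(canon(x));
      std::string first = x, last = x;
      while (true) {
        std::string s1;
        if (succ_count(cur, k, solid, &s1) != 1) break;
        if (pred_count(s1, k, solid) != 1) break;
        if (visited.count(canon(s1))) break; // cycle closure or met other unitig
        cur = s1;
        seq += s1[k - 1];
        covsum += counts[canon(s1)];
        ++nk;
        visited.insert(canon(s1));
        last = s1;
      }
      useq.push_back(seq);
      ucov.push_back(covsum / nk);
      ufirst.push_back(first);
      ulast.push_back(last);
      break;
    }
  }
  // isolated cycles: every node has in=out=1, no start found above
  for (size_t i = 0; i < kept.size(); ++i) {
    const std::string& km = kept[i];
    if (visited.count(km)) continue;
    std::string cur = km;
    std::string seq = km;
    double covsum = counts[km];
    int nk = 1;
    visited.insert(km);
    std::string first = km, last = km;
    while (true) {
      std::string s1;
      if (succ_count(cur, k, solid, &s1) != 1) break;
      if (visited.count(canon(s1))) break;
      cur = s1;
      seq += s1[k - 1];
      covsum += counts[canon(s1)];
      ++nk;
      visited.insert(canon(s1));
      last = s1;
    }
    useq.push_back(seq);
    ucov.push_back(covsum / nk);
    ufirst.push_back(first);
    ulast.push_back(last);
  }

  // oriented start-kmer -> (unitig, orientation)
  std::unordered_map<std::string, OrientedRef> starts;
  int nu = (int)useq.size();
  for (int i = 0; i < nu; ++i) {
    OrientedRef f; f.id = i; f.orient = 0;
    starts[ufirst[i]] = f;
    OrientedRef r; r.id = i; r.orient = 1;
    starts[revcomp(ulast[i])] = r;
  }
  std::vector<int> lfrom, lfor, lto, ltor;
  static const char B[4] = {'A', 'C', 'G', 'T'};
  for (int i = 0; i < nu; ++i) {
    for (int o = 0; o < 2; ++o) {
      std::string tail = (o == 0) ? ulast[i] : revcomp(ufirst[i]);
      std::string y = tail.substr(1) + "A";
      for (int b = 0; b < 4; ++b) {
        y[k - 1] = B[b];
        if (!solid.count(canon(y))) continue;
        std::unordered_map<std::string, OrientedRef>::const_iterator hit =
          starts.find(y);
        if (hit == starts.end()) continue;
        lfrom.push_back(i + 1);
        lfor.push_back(o);
        lto.push_back(hit->second.id + 1);
        ltor.push_back(hit->second.orient);
      }
    }
  }
  return List::create(
    _["seqs"]  = wrap(useq),
    _["cov"]   = wrap(ucov),
    _["links"] = DataFrame::create(
      _["from"] = wrap(lfrom), _["from_or"] = wrap(lfor),
      _["to"]   = wrap(lto),   _["to_or"]   = wrap(ltor)),
    _["k"] = k);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
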