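#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Codon-aware DNA-vs-protein global alignment with frameshift states.
// States are (i nucleotides consumed, j template residues consumed).
// Transitions into (i, j):
//   match      : (i-3, j-1) + blosum(aa(codon), tpl[j-1])
//   fs del 1nt : (i-2, j-1) - fs      (one nt missing from the codon)
//   fs del 2nt : (i-1, j-1) - fs2
//   fs ins 1nt : (i-4, j-1) - fs      (one extra nt inside the codon)
//   fs ins 2nt : (i-5, j-1) - fs2
//   tpl gap    : (i,   j-1) - gap     (template residue unmatched: CODON_GAP)
//   dna gap    : (i-3, j  ) - gap     (extra whole codon in the DNA)
// Trailing DNA (the terminal stop codon and any frameshift remainder) is
// consumed free of charge: the optimum is max_i S(i, m).

static const char CODON_TABLE[65] =
  // AAA AAC AAG AAT ACA ... indexed by 16*b1 + 4*b2 + b3, A=0 C=1 G=2 T=3
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static inline char translate_codon(const char* s) {
  int b1 = base_idx(s[0]), b2 = base_idx(s[1]), b3 = base_idx(s[2]);
  if (b1 < 0 || b2 < 0 || b3 < 0) return 'X';
  return CODON_TABLE[16 * b1 + 4 * b2 + b3];
}

// [[Rcpp::export]]
List codon_align_cpp(std::string dna, std::string tpl,
                     NumericMatrix submat, double fs_penalty,
                     double gap_penalty) {
  const int n = (int)dna.size(), m = (int)tpl.size();
  const double NEG = -1e18;
  const double fs2_penalty = fs_penalty * 1.5;

  // substitution matrix lookup by character
  CharacterVector rn = rownames(submat);
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (int i = 0; i < rn.size(); ++i) idx[(unsigned char)as<std::string>(rn[i])[0]] = i;
  int xi = idx[(unsigned char)'X'];

  std::vector<double> S((size_t)(n + 1) * (m + 1), NEG);
  std::vector<signed char> bt((size_t)(n + 1) * (m + 1), -1);
  // backtrack codes: 0 match, 1 fsdel1, 2 fsins1, 3 fsdel2, 4 fsins2,
  //                  5 tpl gap, 6 dna gap
  static const int di[7] = {3, 2, 4, 1, 5, 0, 3};
  static const int dj[7] = {1, 1, 1, 1, 1, 1, 0};
  auto at = [&](int i, int j) -> size_t { return (size_t)i * (m + 1) + j; };
  S[at(0, 0)] = 0.0;

  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i == 0 && j == 0) continue;
      double best = NEG; int bestk = -1;
      for (int k = 0; k < 7; ++k) {
        int pi = i - di[k], pj = j - dj[k];
        if (pi < 0 || pj < 0) continue;
        double prev = S[at(pi, pj)];
        if (prev <= NEG / 2) continue;
        double sc;
        if (k == 0) {
          char aa = translate_codon(dna.c_str() + i - 3);
          int ai = idx[(unsigned char)aa];
          if (ai < 0) ai = xi;
          int ti = idx[(unsigned char)tpl[j - 1]];
          if (ti < 0) ti = xi;
          sc = prev + submat(ai, ti);
        } else if (k == 1 || k == 2) sc = prev - fs_penalty;
        else if (k == 3 || k == 4) sc = prev - fs2_penalty;
        else sc = prev - gap_penalty;
        if (sc > best) { best = sc; bestk = k; }
      }
      S[at(i, j)] = best;
      bt[at(i, j)] = (signed char)bestk;
    }
  }

  // free trailing DNA: end at the i maximizing S(i, m), largest i on ties
  int end_i = 0; double final_score = NEG;
  for (int i = 0; i <= n; ++i)
    if (S[at(i, m)] >= final_score) { final_score = S[at(i, m)]; end_i = i; }

  // traceback
  std::vector<std::string> ev_kind;
  std::vector<int> ev_pos, ev_shift, ev_detail;
  std::string path_protein;
  int i = end_i, j = m;
  while (i > 0 || j > 0) {
    int k = bt[at(i, j)];
    if (k < 0) break;  // unreachable guard
    if (k == 0) {
      char aa = translate_codon(dna.c_str() + i - 3);
      if (aa == '*') {
        ev_kind.push_back("PREMATURE_STOP");
        ev_pos.push_back(i - 2);       // 1-based codon start
        ev_shift.push_back(0);
        ev_detail.push_back(j);        // template residue index
        aa = 'X';
      }
      path_protein.push_back(aa);
    } else if (k >= 1 && k <= 4) {
      static const char* kinds[4] = {"FRAMESHIFT_DEL", "FRAMESHIFT_INS",
                                     "FRAMESHIFT_DEL", "FRAMESHIFT_INS"};
      static const int shifts[4] = {-1, +1, -2, +2};
      ev_kind.push_back(kinds[k - 1]);
      ev_pos.push_back(i - di[k] + 1);
      ev_shift.push_back(shifts[k - 1]);
      ev_detail.push_back(j);
      path_protein.push_back('X');
    } else if (k == 5) {
      ev_kind.push_back("CODON_GAP");
      ev_pos.push_back(i + 1);
      ev_shift.push_back(0);
      ev_detail.push_back(j);
    }
    i -= di[k]; j -= dj[k];
  }
  std::reverse(path_protein.begin(), path_protein.end());
  std::reverse(ev_kind.begin(), ev_kind.end());
  std::reverse(ev_pos.begin(), ev_pos.end());
  std::reverse(ev_shift.begin(), ev_shift.end());
  std::reverse(ev_detail.begin(), ev_detail.end());

  return List::create(
    _["score"] = final_score,
    _["path_protein"] = path_protein,
    _["events"] = List::create(
      _["kind"] = wrap(ev_kind), _["dna_position"] = wrap(ev_pos),
      _["shift"] = wrap(ev_shift), _["detail"] = wrap(ev_detail)));
}
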