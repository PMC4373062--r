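// Frameshift-aware alignment of a nucleotide query against a reference
// protein, in codon space. Global over the reference, free end gaps on the
// query (so the scored gene may sit anywhere inside a larger region).
// Moves per reference residue: a clean codon (3 nt), frameshifted codons
// consuming 1/2/4/5 nt (single penalized frame-disruption event each),
// codon deletion (0 nt) and codon insertion (3 nt, reference stays put).
// Only the frameshift moves change the reading frame mod 3, so every net
// frame disruption inside the aligned region is forced through a counted
// event. Aligned codons translating to stop are emitted as nonsense events.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static const char CODON_TABLE[65] =
    // AAA AAC AAG AAT ACA ... TTT, index = 16*b1 + 4*b2 + b3 (A0 C1 G2 T3)
    "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline int baseIdx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline char translateCodon(const char* q, int start0) {
  int b1 = baseIdx(q[start0]), b2 = baseIdx(q[start0 + 1]),
      b3 = baseIdx(q[start0 + 2]);
  if (b1 < 0 || b2 < 0 || b3 < 0) return 'X';
  return CODON_TABLE[16 * b1 + 4 * b2 + b3];
}

// move codes stored in the traceback
enum Move : uint8_t { NONE = 0, M3 = 1, F1 = 2, F2 = 3, F4 = 4, F5 = 5,
                      DEL = 6, INS = 7 };

// [[Rcpp::export(name = ".defectAlignCpp")]]
List defectAlignCpp(std::string query, std::string ref,
                    double matchScore = 3.0, double mismatchScore = -1.0,
                    double fsPen = -12.0, double gapPen = -9.0) {
  const int n = (int)query.size();
  const int m = (int)ref.size();
  const double NEG = -1e18;
  const int W = n + 1;
  std::vector<double> H((size_t)(m + 1) * W, NEG);
  std::vector<uint8_t> TB((size_t)(m + 1) * W, NONE);

  // free leading query, charged leading reference deletions
  for (int j = 0; j <= n; ++j) H[j] = 0.0;
  for (int i = 1; i <= m; ++i) {
    H[(size_t)i * W] = i * gapPen;
    TB[(size_t)i * W] = DEL;
  }

  // a query stop against a reference residue is scored below an ordinary
  // mismatch: premature stops are drastic and this keeps spurious stop
  // alignments out of substitution-only explanations of shifted runs
  const double stopScore = 4.0 * mismatchScore;
  auto sub = [&](char refAA, char qAA) {
    if (qAA == 'X') return 0.0;                 // ambiguous codon: neutral
    if (qAA == '*') return stopScore;
    return (refAA == qAA) ? matchScore : mismatchScore;
  };

  for (int i = 1; i <= m; ++i) {
    const char ra = ref[i - 1];
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      double best = NEG;
      uint8_t mv = NONE;
      if (j >= 3) {                             // clean codon
        double s = H[prow + j - 3] + sub(ra, translateCodon(query.c_str(), j - 3));
        if (s > best) { best = s; mv = M3; }
      }
      if (j >= 2) {                             // codon with 1 nt deleted
        double s = H[prow + j - 2] + fsPen;
        if (s > best) { best = s; mv = F2; }
      }
      {                                         // codon with 2 nt deleted
        double s = H[prow + j - 1] + fsPen;
        if (s > best) { best = s; mv = F1; }
      }
      if (j >= 4) {                             // codon with 1 nt inserted
        double s = H[prow + j - 4] + fsPen +
                   sub(ra, translateCodon(query.c_str(), j - 3));
        if (s > best) { best = s; mv = F4; }
      }
      if (j >= 5) {                             // codon with 2 nt inserted
        double s = H[prow + j - 5] + fsPen +
                   sub(ra, translateCodon(query.c_str(), j - 3));
        if (s > best) { best = s; mv = F5; }
      }
      {                                         // reference residue deleted
        double s = H[prow + j] + gapPen;
        if (s > best) { best = s; mv = DEL; }
      }
      if (j >= 3) {                             // extra in-frame query codon
        double s = H[row + j - 3] + gapPen;
        if (s > best) { best = s; mv = INS; }
      }
      H[row + j] = best;
      TB[row + j] = mv;
    }
  }

  // free trailing query: best cell in the last reference row
  int jBest = 0;
  double best = NEG;
  const size_t lrow = (size_t)m * W;
  for (int j = 0; j <= n; ++j)
    if (H[lrow + j] >= best) { best = H[lrow + j]; jBest = j; }

  // traceback
  std::vector<std::string> kind;
  std::vector<int> pos, refPos, mSincePrevFs;
  std::vector<std::string> detail;
  int i = m, j = jBest, mCount = 0;
  struct Ev { std::string kind; int pos; int refPos; std::string detail; int mgap; };
  std::vector<Ev> evs;
  while (i > 0 || (j > 0 && TB[(size_t)i * W + j] != NONE)) {
    uint8_t mv = TB[(size_t)i * W + j];
    if (i == 0) break;                          // remaining query is free lead
    int consumed = 0;
    bool isFs = false;
    std::string det;
    switch (mv) {
      case M3: consumed = 3; break;
      case F2: consumed = 2; isFs = true; det = "del1"; break;
      case F1: consumed = 1; isFs = true; det = "del2"; break;
      case F4: consumed = 4; isFs = true; det = "ins1"; break;
      case F5: consumed = 5; isFs = true; det = "ins2"; break;
      case DEL: consumed = 0; break;
      case INS: consumed = 3; break;
      default: consumed = 0; break;
    }
    int qStart = j - consumed + 1;              // 1-based
    if (mv == M3) {
      // stops inside frameshifted codons (F4/F5) are artifacts of the indel
      // itself and are not separate nonsense events
      char aa = translateCodon(query.c_str(), j - 3);
      if (aa == '*')
        evs.push_back({"nonsense", j - 2, i, std::string(1, ref[i - 1]), -1});
    }
    if (isFs) {
      evs.push_back({"frameshift", qStart, i, det, mCount});
      mCount = 0;
    } else if (mv == M3) {
      ++mCount;
    }
    if (mv == DEL) { --i; }
    else if (mv == INS) { j -= 3; }
    else { --i; j -= consumed; }
    if (mv == NONE) break;
  }
  int alnStart = j + 1;                         // first aligned query nt

  std::reverse(evs.begin(), evs.end());
  // mgap recorded walking backwards = clean codons *after* the event;
  // recompute forward gaps for merging: clean codons between fs events
  // are exactly the mgap stored on the *previous* (in reverse) fs event,
  // i.e. after reversal, the mgap of event k counts M-moves between event k
  // and the next fs event; shift so each fs event knows the gap to the
  // previous fs event.
  int prevGap = -1;
  for (size_t k = 0; k < evs.size(); ++k) {
    if (evs[k].kind != "frameshift") continue;
    int after = evs[k].mgap;                    // M-moves after this event
    evs[k].mgap = prevGap;                      // gap to previous fs (-1 = first)
    prevGap = after;
  }
  for (auto& e : evs) {
    kind.push_back(e.kind);
    pos.push_back(e.pos);
    refPos.push_back(e.refPos);
    detail.push_back(e.detail);
    mSincePrevFs.push_back(e.mgap);
  }
  return List::create(_["score"] = best,
                      _["alnStart"] = alnStart, _["alnEnd"] = jBest,
                      _["kind"] = kind, _["position"] = pos,
                      _["refPos"] = refPos, _["detail"] = detail,
                      _["mSincePrevFs"] = mSincePrevFs);
}
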