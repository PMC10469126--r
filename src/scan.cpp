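#include <Rcpp.h>
#include <cctype>
#include <string>
#include <vector>

using namespace Rcpp;

// 4-bit IUPAC encoding: A=1, C=2, G=4, T=8; ambiguity codes are unions.
static inline int iupac_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': return 8;
    case 'U': return 8;
    case 'R': return 5;   // A/G
    case 'Y': return 10;  // C/T
    case 'S': return 6;   // C/G
    case 'W': return 9;   // A/T
    case 'K': return 12;  // G/T
    case 'M': return 3;   // A/C
    case 'B': return 14;
    case 'D': return 13;
    case 'H': return 11;
    case 'V': return 7;
    case 'N': return 15;
    default:  return -1;
  }
}

// concrete bases only; anything else (incl. ambiguity codes) -> 0
static inline int base_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': return 8;
    default:  return 0;
  }
}

static inline char complement_char(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'R': return 'Y';
    case 'Y': return 'R';
    case 'S': return 'S';
    case 'W': return 'W';
    case 'K': return 'M';
    case 'M': return 'K';
    case 'B': return 'V';
    case 'V': return 'B';
    case 'D': return 'H';
    case 'H': return 'D';
    default:  return 'N';
  }
}

// [[Rcpp::export(name = ".scan_sequences_cpp")]]
List scan_sequences_cpp(CharacterVector sequences,
                        std::string protospacer,
                        std::string pam,
                        int max_mm,
                        bool both_strands) {
  const int P = static_cast<int>(protospacer.size());
  const int K = static_cast<int>(pam.size());
  const int L = P + K;

  // protospacer as concrete base masks (validated on the R side)
  std::vector<int> proto_mask(P), proto_comp_mask(P);
  for (int p = 0; p < P; ++p) {
    proto_mask[p] = base_mask(protospacer[p]);
    if (proto_mask[p] == 0) stop("protospacer must contain only A/C/G/T");
    proto_comp_mask[p] = base_mask(complement_char(protospacer[p]));
  }
  std::vector<int> pam_mask(K), pam_comp_mask(K);
  for (int j = 0; j < K; ++j) {
    pam_mask[j] = iupac_mask(pam[j]);
    if (pam_mask[j] < 0) stop("invalid IUPAC symbol in PAM pattern");
    // mask of the complement symbol, for minus-strand matching on the forward sequence
    pam_comp_mask[j] = iupac_mask(complement_char(pam[j]));
  }

  std::vector<int> out_contig, out_start, out_mm;
  std::vector<std::string> out_strand, out_site;

  const int n_seq = sequences.size();
  for (int s = 0; s < n_seq; ++s) {
    std::string seq = as<std::string>(sequences[s]);
    const int n = static_cast<int>(seq.size());
    if (n < L) continue;
    std::vector<int> smask(n);
    std::vector<char> up(n);
    for (int i = 0; i < n; ++i) {
      up[i] = static_cast<char>(std::toupper(static_cast<unsigned char>(seq[i])));
      smask[i] = base_mask(up[i]);
    }

    for (int i = 0; i + L <= n; ++i) {
      // ---- plus strand: protospacer at [i, i+P), PAM at [i+P, i+L)
      bool pam_ok = true;
      for (int j = 0; j < K; ++j) {
        int bm = smask[i + P + j];
        if (bm == 0 || (bm & pam_mask[j]) == 0) { pam_ok = false; break; }
      }
      if (pam_ok) {
        int mm = 0;
        for (int p = 0; p < P && mm <= max_mm; ++p) {
          int bm = smask[i + p];
          if (bm == 0 || bm != proto_mask[p]) ++mm;
        }
        if (mm <= max_mm) {
          std::string site(L, 'N');
          for (int p = 0; p < P; ++p) {
            char c = up[i + p];
            int bm = smask[i + p];
            site[p] = (bm == 0 || bm != proto_mask[p])
              ? static_cast<char>(std::tolower(static_cast<unsigned char>(c))) : c;
          }
          for (int j = 0; j < K; ++j) site[P + j] = up[i + P + j];
          out_contig.push_back(s + 1);
          out_start.push_back(i);
          out_strand.push_back("+");
          out_site.push_back(site);
          out_mm.push_back(mm);
        }
      }

      if (!both_strands) continue;

      // ---- minus strand: binding-strand window is the reverse complement of
      // forward [i, i+L). On the forward strand the complemented PAM sits at
      // [i, i+K) (reversed) and the complemented protospacer at [i+K, i+L)
      // (reversed).
      pam_ok = true;
      for (int j = 0; j < K; ++j) {
        int bm = smask[i + K - 1 - j];
        if (bm == 0 || (bm & pam_comp_mask[j]) == 0) { pam_ok = false; break; }
      }
      if (!pam_ok) continue;
      int mm = 0;
      for (int p = 0; p < P && mm <= max_mm; ++p) {
        int bm = smask[i + K + (P - 1 - p)];
        if (bm == 0 || bm != proto_comp_mask[p]) ++mm;
      }
      if (mm > max_mm) continue;
      std::string site(L, 'N');
      for (int p = 0; p < P; ++p) {
        int fwd = i + K + (P - 1 - p);
        char c = complement_char(up[fwd]);
        int bm = smask[fwd];
        site[p] = (bm == 0 || bm != proto_comp_mask[p])
          ? static_cast<char>(std::tolower(static_cast<unsigned char>(c))) : c;
      }
      for (int j = 0; j < K; ++j) site[P + j] = complement_char(up[i + K - 1 - j]);
      out_contig.push_back(s + 1);
      out_start.push_back(i);
      out_strand.push_back("-");
      out_site.push_back(site);
      out_mm.push_back(mm);
    }
  }

  return List::create(
    _["contig_index"] = wrap(out_contig),
    _["start"] = wrap(out_start),
    _["strand"] = wrap(out_strand),
    _["site_sequence"] = wrap(out_site),
    _["mm_count"] = wrap(out_mm));
}

// Positional mismatch count between a concrete candidate window and the
// protospacer; any non-ACGT candidate base is a mismatch.
// [[Rcpp::export(name = ".count_mismatches_cpp")]]
IntegerVector count_mismatches_cpp(CharacterVector candidate, std::string protospacer) {
  const int P = static_cast<int>(protospacer.size());
  std::vector<int> proto_mask(P);
  for (int p = 0; p < P; ++p) {
    proto_mask[p] = base_mask(protospacer[p]);
    if (proto_mask[p] == 0) stop("protospacer must contain only A/C/G/T");
  }
  IntegerVector out(candidate.size());
  for (int i = 0; i < candidate.size(); ++i) {
    std::string cand = as<std::string>(candidate[i]);
    if (static_cast<int>(cand.size()) != P)
      stop("candidate and protospacer must have equal length");
    int mm = 0;
    for (int p = 0; p < P; ++p) {
      int bm = base_mask(cand[p]);
      if (bm == 0 || bm != proto_mask[p]) ++mm;
    }
    out[i] = mm;
  }
  return out;
}

// IUPAC pattern match of a concrete window; non-ACGT window bases never match.
// [[Rcpp::export(name = ".match_pam_cpp")]]
LogicalVector match_pam_cpp(CharacterVector window, std::string pattern) {
  const int K = static_cast<int>(pattern.size());
  std::vector<int> pmask(K);
  for (int j = 0; j < K; ++j) {
    pmask[j] = iupac_mask(pattern[j]);
    if (pmask[j] < 0) stop("invalid IUPAC symbol in PAM pattern");
  }
  LogicalVector out(window.size());
  for (int i = 0; i < window.size(); ++i) {
    std::string w = as<std::string>(window[i]);
    if (static_cast<int>(w.size()) != K)
      stop("window and pattern must have equal length");
    bool ok = true;
    for (int j = 0; j < K; ++j) {
      int bm = base_mask(w[j]);
      if (bm == 0 || (bm & pmask[j]) == 0) { ok = false; break; }
    }
    out[i] = ok;
  }
  return out;
}
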