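#include <Rcpp.h>
using namespace Rcpp;

// Global alignment with affine gaps (Gotoh). A gap of length L costs
// gap_open + L * gap_extend (linear scoring = gap_open 0). Deterministic
// traceback with tie order diagonal (M) > up (gap in b) > left (gap in a).

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18, EPS = 1e-9;
  const double go = gap_open + gap_extend;   // first gap column

  CharacterVector rn = rownames(submat);
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (int i = 0; i < rn.size(); ++i)
    idx[(unsigned char)as<std::string>(rn[i])[0]] = i;

  std::vector<double> M((size_t)(n + 1) * (m + 1), NEG), Ix(M), Iy(M);
  auto at = [&](int i, int j) -> size_t { return (size_t)i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) Ix[at(i, 0)] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Iy[at(0, j)] = -(gap_open + j * gap_extend);

  for (int i = 1; i <= n; ++i) {
    int ai = idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      int bi = idx[(unsigned char)b[j - 1]];
      double dM = M[at(i - 1, j - 1)], dX = Ix[at(i - 1, j - 1)],
             dY = Iy[at(i - 1, j - 1)];
      double dbest = std::max(dM, std::max(dX, dY));
      M[at(i, j)] = (dbest <= NEG / 2) ? NEG : dbest + submat(ai, bi);
      double x1 = M[at(i - 1, j)] - go, x2 = Ix[at(i - 1, j)] - gap_extend,
             x3 = Iy[at(i - 1, j)] - go;
      Ix[at(i, j)] = std::max(x1, std::max(x2, x3));
      double y1 = M[at(i, j - 1)] - go, y2 = Iy[at(i, j - 1)] - gap_extend,
             y3 = Ix[at(i, j - 1)] - go;
      Iy[at(i, j)] = std::max(y1, std::max(y2, y3));
    }
  }

  double sM = M[at(n, m)], sX = Ix[at(n, m)], sY = Iy[at(n, m)];
  double score = std::max(sM, std::max(sX, sY));
  int state = (sM + EPS >= score) ? 0 : ((sX + EPS >= score) ? 1 : 2);

  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      int ai = idx[(unsigned char)a[i - 1]], bi = idx[(unsigned char)b[j - 1]];
      double need = M[at(i, j)] - submat(ai, bi);
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      if (std::fabs(M[at(i, j)] - need) < EPS) state = 0;
      else if (std::fabs(Ix[at(i, j)] - need) < EPS) state = 1;
      else state = 2;
    } else if (state == 1) {
      double cur = Ix[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
      if (std::fabs(M[at(i, j)] - (cur + go)) < EPS) state = 0;
      else if (std::fabs(Ix[at(i, j)] - (cur + gap_extend)) < EPS) state = 1;
      else state = 2;
    } else {
      double cur = Iy[at(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
      if (std::fabs(M[at(i, j)] - (cur + go)) < EPS) state = 0;
      else if (std::fabs(Iy[at(i, j)] - (cur + gap_extend)) < EPS) state = 2;
      else state = 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  int n_match = 0, n_mutual = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] != '-' && rb[k] != '-') {
      ++n_mutual;
      if (ra[k] == rb[k]) ++n_match;
    }
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score, _["n_match"] = n_match,
                      _["n_mutual"] = n_mutual);
}
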