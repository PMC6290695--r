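#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Joe-Kuo (new-joe-kuo-6) primitive polynomials and initial direction
// numbers for dimensions 2..10; dimension 1 is the van der Corput sequence.
static const int JK_S[9] = {1, 2, 3, 3, 4, 4, 5, 5, 5};
static const int JK_A[9] = {0, 1, 1, 2, 1, 4, 2, 4, 7};
static const int JK_M[9][5] = {
    {1, 0, 0, 0, 0},
    {1, 3, 0, 0, 0},
    {1, 3, 1, 0, 0},
    {1, 1, 1, 0, 0},
    {1, 1, 3, 3, 0},
    {1, 3, 5, 13, 0},
    {1, 1, 5, 5, 17},
    {1, 1, 5, 5, 5},
    {1, 1, 7, 11, 19}};

static const int SOBOL_MAXDIM = 10;
static const int NBITS = 31;

// [[Rcpp::export]]
NumericMatrix sobol_points_cpp(int n_points, int n_dims) {
  if (n_dims < 1 || n_dims > SOBOL_MAXDIM)
    stop("sobol_sequence supports 1..%d dimensions", SOBOL_MAXDIM);
  if (n_points < 1) stop("n_points must be >= 1");

  // direction numbers v[d][k], k = 0..NBITS-1, scaled into the top bits
  std::vector< std::vector<uint32_t> > v(n_dims, std::vector<uint32_t>(NBITS));
  for (int d = 0; d < n_dims; ++d) {
    if (d == 0) {
      for (int k = 0; k < NBITS; ++k) v[d][k] = 1u << (NBITS - 1 - k);
    } else {
      int s = JK_S[d - 1];
      int a = JK_A[d - 1];
      for (int k = 0; k < s && k < NBITS; ++k)
        v[d][k] = ((uint32_t)JK_M[d - 1][k]) << (NBITS - 1 - k);
      for (int k = s; k < NBITS; ++k) {
        uint32_t val = v[d][k - s] ^ (v[d][k - s] >> s);
        for (int i = 1; i < s; ++i)
          if ((a >> (s - 1 - i)) & 1) val ^= v[d][k - i];
        v[d][k] = val;
      }
    }
  }

  // Gray-code generation; the all-zeros initial point is skipped.
  NumericMatrix out(n_points, n_dims);
  std::vector<uint32_t> x(n_dims, 0u);
  const double scale = 1.0 / 2147483648.0; // 2^-31
  for (int i = 0; i < n_points; ++i) {
    // c = index of lowest zero bit of i (0-based), drives point i+1
    uint32_t ii = (uint32_t)i;
    int c = 0;
    while (ii & 1u) { ii >>= 1; ++c; }
    for (int d = 0; d < n_dims; ++d) {
      x[d] ^= v[d][c];
      out(i, d) = x[d] * scale;
    }
  }
  return out;
}
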