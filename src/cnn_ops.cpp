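// Convolutional primitives for the analysis-stage network.
// 3x3 same-padding convolution and 2x2 max pooling, with exact backward
// passes; im2col + BLAS matmul keeps CPU training of the test-profile
// encoder within minutes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col3(const cube& input) {
  const uword H = input.n_rows, W = input.n_cols, C = input.n_slices;
  mat cols(H * W, 9 * C, fill::zeros);
  for (uword ch = 0; ch < C; ++ch) {
    const mat& sl = input.slice(ch);
    for (int kr = -1; kr <= 1; ++kr) {
      for (int kc = -1; kc <= 1; ++kc) {
        const uword col = ch * 9 + (kr + 1) * 3 + (kc + 1);
        for (uword c = 0; c < W; ++c) {
          const int sc = (int)c + kc;
          if (sc < 0 || sc >= (int)W) continue;
          for (uword r = 0; r < H; ++r) {
            const int sr = (int)r + kr;
            if (sr < 0 || sr >= (int)H) continue;
            cols(c * H + r, col) = sl(sr, sc);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv3x3_forward")]]
arma::cube conv3x3_forward(const arma::cube& input, const arma::mat& weight,
                           const arma::vec& bias) {
  const uword H = input.n_rows, W = input.n_cols;
  const uword Cout = weight.n_cols;
  mat cols = im2col3(input);
  mat out = cols * weight;
  out.each_row() += bias.t();
  cube res(H, W, Cout);
  for (uword k = 0; k < Cout; ++k)
    res.slice(k) = reshape(out.col(k), H, W);
  return res;
}

// [[Rcpp::export(name = ".conv3x3_backward")]]
Rcpp::List conv3x3_backward(const arma::cube& input, const arma::mat& weight,
                            const arma::cube& grad_out) {
  const uword H = input.n_rows, W = input.n_cols, Cin = input.n_slices;
  const uword Cout = grad_out.n_slices;
  mat G(H * W, Cout);
  for (uword k = 0; k < Cout; ++k)
    G.col(k) = vectorise(grad_out.slice(k));
  mat cols = im2col3(input);
  mat gradW = cols.t() * G;
  vec gradB = sum(G, 0).t();
  // scatter G * W^T back to input positions
  mat P = G * weight.t();              // (H*W) x (9*Cin)
  cube gradIn(H, W, Cin, fill::zeros);
  for (uword ch = 0; ch < Cin; ++ch) {
    mat& gs = gradIn.slice(ch);
    for (int kr = -1; kr <= 1; ++kr) {
      for (int kc = -1; kc <= 1; ++kc) {
        const uword col = ch * 9 + (kr + 1) * 3 + (kc + 1);
        for (uword c = 0; c < W; ++c) {
          const int sc = (int)c + kc;
          if (sc < 0 || sc >= (int)W) continue;
          for (uword r = 0; r < H; ++r) {
            const int sr = (int)r + kr;
            if (sr < 0 || sr >= (int)H) continue;
            gs(sr, sc) += P(c * H + r, col);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("grad_input") = gradIn,
                            Rcpp::Named("grad_weight") = gradW,
                            Rcpp::Named("grad_bias") = gradB);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
Rcpp::List maxpool2_forward(const arma::cube& input) {
  const uword H = input.n_rows, W = input.n_cols, C = input.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  ucube arg(Ho, Wo, C);  // 0..3: (dr, dc) = (idx %% 2, idx / 2)
  for (uword ch = 0; ch < C; ++ch) {
    const mat& sl = input.slice(ch);
    for (uword c = 0; c < Wo; ++c) {
      for (uword r = 0; r < Ho; ++r) {
        double best = sl(2 * r, 2 * c); uword bi = 0;
        for (uword dc = 0; dc < 2; ++dc)
          for (uword dr = 0; dr < 2; ++dr) {
            double v = sl(2 * r + dr, 2 * c + dc);
            if (v > best) { best = v; bi = dc * 2 + dr; }
          }
        out(r, c, ch) = best;
        arg(r, c, ch) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("output") = out,
                            Rcpp::Named("argmax") = arg);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
arma::cube maxpool2_backward(const arma::ucube& argmax,
                             const arma::cube& grad_out,
                             int in_h, int in_w) {
  const uword Ho = grad_out.n_rows, Wo = grad_out.n_cols, C = grad_out.n_slices;
  cube gradIn(in_h, in_w, C, fill::zeros);
  for (uword ch = 0; ch < C; ++ch) {
    for (uword c = 0; c < Wo; ++c) {
      for (uword r = 0; r < Ho; ++r) {
        const uword bi = argmax(r, c, ch);
        gradIn(2 * r + bi % 2, 2 * c + bi / 2, ch) += grad_out(r, c, ch);
      }
    }
  }
  return gradIn;
}
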