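## shared fixtures for the suite
default_method <- fida_method()

## independent mass-action oracle: bisection on the complex concentration
## x solving (I - x)(B - x) = kd * x on [0, min(I, B)]
fraction_bound_bisect <- function(kd, I, B, iters = 200) {
  if (B == 0 || I == 0) return(if (I == 0) B / (B + kd) else 0)
  f <- function(x) (I - x) * (B - x) - kd * x
  lo <- 0; hi <- min(I, B)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / I
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
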