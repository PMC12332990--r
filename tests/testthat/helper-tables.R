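# Synthetic feature tables with planted signal columns, used by the
# radiomics-selection and classifier tests.

make_signal_table <- function(n = 200, p_noise = 12, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(stats::rnorm(n * p_noise), n)
  colnames(X) <- sprintf("noise_%02d", seq_len(p_noise))
  sig <- sapply(1:3, function(k) y * 1.5 + stats::rnorm(n, 0, 0.7))
  colnames(sig) <- sprintf("signal_%d", 1:3)
  out <- data.frame(id = sprintf("p%03d", seq_len(n)), side = "left",
                    label = y, split = rep(c("train", "valid"), length.out = n),
                    sig, X, check.names = FALSE)
  class(out) <- c("FeatureTable", "data.frame")
  out
}
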