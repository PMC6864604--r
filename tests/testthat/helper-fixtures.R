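# Shared helpers: tiny images and reference tables built in code.

# small solid-colour image
solid_image <- function(w, h, r, g, b, a = 255) {
  rgb_image(matrix(r, h, w), matrix(g, h, w), matrix(b, h, w),
            alpha = matrix(a, h, w))
}

# the published line relating T/C to log10(quantity / 10 fg)
published_model <- function() calibration_model(slope = 0.203, intercept = 0.0118)

# confusion matrix printed for the held-out strip set: one 10 pg strip
# called 100 pg, everything else on the diagonal (10 readings per class)
published_test_confusion <- function() {
  cm <- diag(10L, 5)
  rownames(cm) <- colnames(cm) <- c("100000", "10000", "1000", "100", "10")
  cm[2, 1] <- 1L
  cm[2, 2] <- 9L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

# published per-class sd of T/C ratios (pooled over the three sets)
published_class_sd <- c(`100` = 0.021829, `1000` = 0.035544,
                        `10000` = 0.055213, `100000` = 0.055011)
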