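# Shared fixtures, built in code.

# five entities, distinct scores, labels 1,1,0,1,0 from the top:
# anchors (tp, fp) = (1,0), (2,0), (2,1), (3,1), (3,2)
d1 <- function() {
  scoredLabels(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0))
}

# every entity gets the same score: a single all-tied anchor
constClassifier <- function(P = 3, N = 2) {
  scoredLabels(rep(0.5, P + N), rep(c(1L, 0L), c(P, N)))
}

# random score/label set; withTies draws scores from few discrete levels
randomScored <- function(n, pPos = 0.5, withTies = FALSE) {
  lab <- stats::rbinom(n, 1, pPos)
  if (sum(lab) == 0) lab[sample.int(n, 1)] <- 1L
  s <- if (withTies) sample(seq(0, 1, by = 0.25), n, replace = TRUE)
       else stats::runif(n)
  scoredLabels(s, lab)
}
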