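## Independent geometric oracle for Poincare-section crossings: parametric
## segment/line intersection (solve for the crossing parameter t and require
## it strictly inside the open segment), plus a dense-sampling distance check
## for the circular section. Deliberately different algebra from the
## implementation's sign-change / projection formulas.
oracle_poincare <- function(points, plane, r = 0.001) {
  normals <- list(PP1 = c(0, 1), PP2 = c(1, 0),
                  PP3 = c(-1, 1), PP4 = c(1, 1))
  n <- nrow(points)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    if (plane == "PP5") {
      t <- seq(0, 1, length.out = 2001L)
      seg <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
      if (min(sqrt(rowSums(seg^2))) < r) count <- count + 1L
    } else {
      nv <- normals[[plane]]
      fa <- sum(nv * a); fb <- sum(nv * b)
      denom <- fa - fb
      if (denom != 0) {
        t <- fa / denom
        if (t > 0 && t < 1 && fa != 0 && fb != 0) count <- count + 1L
      }
    }
  }
  count
}

## Exact discrete mutual information (bits) of a joint probability table.
oracle_discrete_mi <- function(joint) {
  joint <- joint / sum(joint)
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint)))
    if (joint[i, j] > 0)
      s <- s + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
  s
}

## Numeric fingerprint of a matrix, used for distinctness checks.
fingerprint <- function(m) paste(format(c(mean(m), stats::sd(m), min(m),
                                          max(m)), digits = 17),
                                 collapse = "|")
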