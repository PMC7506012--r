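# Independent brute-force oracles. These deliberately share no code with
# the package implementations: explicit queue-based flood fill for the
# calcium score, and literal rule tables for CAD-RADS and the stress
# score banding.

# Agatston score by per-pixel flood fill on each slice
oracle_agatston <- function(vol) {
  arr <- vol$data
  d <- dim(arr)
  pix <- vol$spacing[1] * vol$spacing[2]
  tf <- vol$spacing[3] / 3
  total <- 0
  n_lesions <- 0
  for (k in seq_len(d[3])) {
    sl <- arr[, , k]
    seen <- matrix(FALSE, d[1], d[2])
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (seen[i, j] || is.na(sl[i, j]) || sl[i, j] < 130) next
      # breadth-first collection of the 4-connected component
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      pts <- matrix(c(i, j), ncol = 2)
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (step in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + step
          if (q[1] < 1 || q[1] > d[1] || q[2] < 1 || q[2] > d[2]) next
          if (seen[q[1], q[2]] || is.na(sl[q[1], q[2]]) ||
              sl[q[1], q[2]] < 130) next
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1]] <- q
          pts <- rbind(pts, q)
        }
      }
      area <- nrow(pts) * pix
      if (area < 1) next
      peak <- max(sl[pts])
      w <- if (peak >= 400) 4 else if (peak >= 300) 3 else
        if (peak >= 200) 2 else 1
      total <- total + area * w * tf
      n_lesions <- n_lesions + 1
    }
  }
  list(total = total, n_lesions = n_lesions)
}

# CAD-RADS as a literal transcription of the published category list
oracle_cad_rads <- function(vessels, lm) {
  if (any(c(vessels, lm) == 100)) return("5")
  if (lm >= 50) return("4B")
  sev <- sum(vessels >= 70)
  if (sev == 3) return("4B")
  if (sev == 1 || sev == 2) return("4A")
  mx <- max(c(vessels, lm))
  if (mx >= 50 && mx <= 69) return("3")
  if (mx >= 25 && mx <= 49) return("2")
  if (mx >= 1) return("1")
  "0"
}

# stress-score banding as a lookup over the printed category bounds
oracle_segment_score <- function(x) {
  if (x > 0.75) 0L
  else if (x > 0.675 && x <= 0.75) 1L
  else if (x > 0.60 && x <= 0.675) 2L
  else 3L
}
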