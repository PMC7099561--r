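# Independent brute-force oracles used to cross-check the package's
# morphology and metric implementations. Deliberately written as plain
# flood fills / pixel loops, sharing no code with the implementation.

# Connected-component labelling by repeated min-label propagation.
oracle_label <- function(mask, eight = TRUE) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nextlab <- 0L
  shifts4 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  shifts8 <- c(shifts4, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  shifts <- if (eight) shifts8 else shifts4
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (mask[r0, c0] == 0 || lab[r0, c0] != 0) next
    nextlab <- nextlab + 1L
    frontier <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- nextlab
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (i in seq_len(nrow(frontier))) {
        for (s in shifts) {
          r <- frontier[i, 1] + s[1]; c <- frontier[i, 2] + s[2]
          if (r >= 1 && r <= H && c >= 1 && c <= W &&
              mask[r, c] != 0 && lab[r, c] == 0) {
            lab[r, c] <- nextlab
            nxt <- rbind(nxt, c(r, c))
          }
        }
      }
      frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else nxt
    }
  }
  lab
}

oracle_largest <- function(mask) {
  lab <- oracle_label(mask, eight = TRUE)
  n <- max(lab)
  if (n == 0) return(mask)
  sizes <- vapply(seq_len(n), function(l) sum(lab == l), numeric(1))
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    # smallest pixel in row-major (row, then col) order
    first <- vapply(cand, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      min((idx[, 1] - 1) * ncol(mask) + idx[, 2])
    }, numeric(1))
    cand <- cand[which.min(first)]
  }
  matrix(as.integer(lab == cand), nrow(mask), ncol(mask))
}

oracle_fill <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  reach <- matrix(FALSE, H, W)
  frontier <- NULL
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if ((r == 1 || r == H || c == 1 || c == W) && mask[r, c] == 0) {
      reach[r, c] <- TRUE
      frontier <- rbind(frontier, c(r, c))
    }
  }
  while (!is.null(frontier) && nrow(frontier) > 0) {
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- frontier[i, 1] + s[1]; c <- frontier[i, 2] + s[2]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] == 0 && !reach[r, c]) {
          reach[r, c] <- TRUE
          nxt <- rbind(nxt, c(r, c))
        }
      }
    }
    frontier <- nxt
  }
  matrix(as.integer(mask == 1L | !reach), H, W)
}

oracle_n_components <- function(mask, eight = TRUE) {
  max(oracle_label(mask, eight))
}

oracle_n_holes <- function(mask) {
  # interior background components under 4-connectivity
  bg <- 1L - mask
  lab <- oracle_label(bg, eight = FALSE)
  if (max(lab) == 0) return(0L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  length(setdiff(seq_len(max(lab)), border))
}

# Pixel-loop confusion counts and metrics.
oracle_metrics <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (r in seq_len(nrow(pred))) for (c in seq_len(ncol(pred))) {
    if (pred[r, c] == 1 && gt[r, c] == 1) tp <- tp + 1L
    else if (pred[r, c] == 1 && gt[r, c] == 0) fp <- fp + 1L
    else if (pred[r, c] == 0 && gt[r, c] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       dsc = if (fp + 2 * tp + fn > 0) 2 * tp / (fp + 2 * tp + fn) else 1,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# A smoothed random probability map (spatially correlated, values in [0,1]).
random_probmap <- function(h, w) {
  x <- matrix(runif(h * w), h, w)
  for (i in 1:2) x <- fazseg:::blur3(x)
  (x - min(x)) / (max(x) - min(x) + 1e-12)
}

# Small cached cohort shared by tests that only need plausible samples.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(2, 1, seed = 7,
                                                  size = c(64, 64))
    cache
  }
})
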