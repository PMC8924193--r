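# Independent per-definition oracles. These deliberately re-implement the
# contracts with naive data structures (linear scans, double loops) so they
# share no code path with the package implementations they check.

# priority-flood watershed oracle: linear-scan frontier, (elevation, FIFO)
# pop order, lexicographic frontier construction and label selection
oracle_watershed <- function(elev, markers, mask = NULL) {
  nr <- nrow(elev); nc <- ncol(elev)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  lab <- markers
  qe <- numeric(0); qs <- numeric(0); qr <- integer(0); qc <- integer(0)
  seq_ctr <- 0
  nbrs <- function(r, c) {
    # lexicographic (row, col) order: up, left, right, down
    out <- list()
    for (k in list(c(r - 1L, c), c(r, c - 1L), c(r, c + 1L), c(r + 1L, c)))
      if (k[1] >= 1L && k[1] <= nr && k[2] >= 1L && k[2] <= nc)
        out[[length(out) + 1L]] <- k
    out
  }
  push <- function(r, c) {
    qe <<- c(qe, elev[r, c]); qs <<- c(qs, seq_ctr)
    qr <<- c(qr, r); qc <<- c(qc, c)
    seq_ctr <<- seq_ctr + 1
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (lab[r, c] > 0L)
      for (k in nbrs(r, c))
        if (lab[k[1], k[2]] <= 0L && mask[k[1], k[2]]) push(k[1], k[2])
  }
  while (length(qe)) {
    i <- order(qe, qs)[1]
    r <- qr[i]; c <- qc[i]
    qe <- qe[-i]; qs <- qs[-i]; qr <- qr[-i]; qc <- qc[-i]
    if (lab[r, c] > 0L) next
    assigned <- 0L
    for (k in nbrs(r, c))
      if (lab[k[1], k[2]] > 0L) { assigned <- lab[k[1], k[2]]; break }
    if (assigned == 0L) next
    lab[r, c] <- assigned
    for (k in nbrs(r, c))
      if (lab[k[1], k[2]] <= 0L && mask[k[1], k[2]]) push(k[1], k[2])
  }
  lab
}

# exhaustive Otsu: argmax of between-class variance over every candidate
# threshold (foreground strictly greater)
oracle_otsu <- function(values, maxv = 255L) {
  v <- as.integer(values)
  best_t <- NA_integer_; best_bcv <- -Inf
  for (t in 0:maxv) {
    bg <- v[v <= t]; fg <- v[v > t]
    if (!length(bg) || !length(fg)) next
    w0 <- length(bg) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (bcv > best_bcv) { best_bcv <- bcv; best_t <- t }
  }
  best_t
}

# naive boundary pixels of one object: 4-neighbour outside (frame = outside)
oracle_boundary_points <- function(inst, label) {
  nr <- nrow(inst); nc <- ncol(inst)
  pts <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (inst[r, c] != label) next
    nb_out <- FALSE
    for (k in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
      if (k[1] < 1L || k[1] > nr || k[2] < 1L || k[2] > nc ||
          inst[k[1], k[2]] != label) { nb_out <- TRUE; break }
    }
    if (nb_out) pts <- rbind(pts, c(r, c))
  }
  pts
}

oracle_hausdorff <- function(a, b) {
  # full pairwise distance matrix, then the two directed sup-inf terms
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

oracle_dice <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# per-definition object-Dice: size-weighted bidirectional, maximal-overlap
# matching with ties to the lowest label
oracle_object_dice <- function(S, G) {
  s_labs <- sort(setdiff(unique(as.vector(S)), 0L))
  g_labs <- sort(setdiff(unique(as.vector(G)), 0L))
  if (!length(s_labs) && !length(g_labs)) return(1)
  side <- function(A, B, a_labs, b_labs) {
    if (!length(a_labs)) return(0)
    areas <- sapply(a_labs, function(l) sum(A == l))
    tot <- 0
    for (i in seq_along(a_labs)) {
      ov <- sapply(b_labs, function(m) sum(A == a_labs[i] & B == m))
      d <- if (!length(b_labs) || max(ov) == 0L) 0 else {
        m <- b_labs[which.max(ov)]
        oracle_dice(A == a_labs[i], B == m)
      }
      tot <- tot + (areas[i] / sum(areas)) * d
    }
    tot
  }
  0.5 * (side(S, G, s_labs, g_labs) + side(G, S, g_labs, s_labs))
}

oracle_object_hausdorff <- function(S, G) {
  s_labs <- sort(setdiff(unique(as.vector(S)), 0L))
  g_labs <- sort(setdiff(unique(as.vector(G)), 0L))
  if (!length(s_labs) && !length(g_labs)) return(0)
  if (!length(s_labs) || !length(g_labs)) return(NA_real_)
  side <- function(A, B, a_labs, b_labs) {
    areas <- sapply(a_labs, function(l) sum(A == l))
    tot <- 0
    for (i in seq_along(a_labs)) {
      ov <- sapply(b_labs, function(m) sum(A == a_labs[i] & B == m))
      m <- if (max(ov) > 0L) b_labs[which.max(ov)] else {
        hs <- sapply(b_labs, function(mm)
          oracle_hausdorff(oracle_boundary_points(A, a_labs[i]),
                           oracle_boundary_points(B, mm)))
        b_labs[which.min(hs)]
      }
      h <- oracle_hausdorff(oracle_boundary_points(A, a_labs[i]),
                            oracle_boundary_points(B, m))
      tot <- tot + (areas[i] / sum(areas)) * h
    }
    tot
  }
  0.5 * (side(S, G, s_labs, g_labs) + side(G, S, g_labs, s_labs))
}
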