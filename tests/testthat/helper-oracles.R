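# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package
# internals: the Otsu oracle loops over explicit cut points, the maxima
# oracle floods level sets per candidate, the volume oracle assigns
# elements one by one.

# Exhaustive Otsu: try every threshold t, class0 = {v < t}, class1 =
# {v >= t}, maximize w0*w1*(mu0-mu1)^2, lowest tie wins (ascending scan
# keeps the first maximizer; a relative guard absorbs float noise between
# equivalent partitions).
oracle_otsu <- function(v, cuts = 1:(max(v) + 1)) {
  best_t <- NA_real_
  best_s <- -Inf
  n <- length(v)
  for (t in cuts) {
    lo <- v[v < t]
    hi <- v[v >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    s <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (s > best_s * (1 + 1e-12) + 1e-12) {
      best_s <- s
      best_t <- t
    }
  }
  best_t
}

# Flood a level set: all pixels with value >= level, 8-connected to the
# seed, staying inside mask. Vectorized dilation loop.
flood_level <- function(img, mask, seed_rc, level) {
  nr <- nrow(img); nc <- ncol(img)
  eligible <- mask & img >= level
  reg <- matrix(FALSE, nr, nc)
  reg[seed_rc[1], seed_rc[2]] <- TRUE
  repeat {
    grown <- reg
    # 8-neighbour dilation via shifts
    for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
      src_r <- max(1, 1 + sh[1]):min(nr, nr + sh[1])
      dst_r <- max(1, 1 - sh[1]):min(nr, nr - sh[1])
      src_c <- max(1, 1 + sh[2]):min(nc, nc + sh[2])
      dst_c <- max(1, 1 - sh[2]):min(nc, nc - sh[2])
      grown[dst_r, dst_c] <- grown[dst_r, dst_c] | reg[src_r, src_c]
    }
    grown <- grown & eligible
    if (all(grown == reg)) return(reg)
    reg <- grown
  }
}

# Candidate summit plateaus: 8-connected equal-value components inside the
# mask none of whose members touches a strictly higher in-mask pixel.
# Representative pixel: topmost, then leftmost.
oracle_summits <- function(img, mask) {
  nr <- nrow(img); nc <- ncol(img)
  visited <- matrix(FALSE, nr, nc)
  out <- list()
  for (cc0 in seq_len(nc)) for (rr0 in seq_len(nr)) {
    if (!mask[rr0, cc0] || visited[rr0, cc0]) next
    v <- img[rr0, cc0]
    plateau <- flood_level(img, mask & img == v, c(rr0, cc0), v)
    visited[plateau] <- TRUE
    # does any plateau member touch a strictly higher masked pixel?
    higher <- FALSE
    idx <- which(plateau)
    pr <- (idx - 1) %% nr + 1
    pc <- (idx - 1) %/% nr + 1
    for (i in seq_along(idx)) {
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- pr[i] + dr; c2 <- pc[i] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (mask[r2, c2] && img[r2, c2] > v) higher <- TRUE
      }
      if (higher) break
    }
    if (!higher) {
      rep_i <- order(pr, pc)[1]
      out[[length(out) + 1]] <- list(row = pr[rep_i], col = pc[rep_i],
                                     value = v)
    }
  }
  out
}

# Prominence of each summit: descend through the levels present in the
# summit's connected mask region; the first (highest) level whose flooded
# region contains a strictly higher pixel, or an equal-valued summit with
# an earlier (topmost-leftmost) representative, is the saddle. A summit
# that never connects gets value - region minimum.
oracle_find_maxima <- function(img, mask, tolerance) {
  summits <- oracle_summits(img, mask)
  if (length(summits) == 0)
    return(data.frame(row = numeric(0), col = numeric(0),
                      value = numeric(0), prominence = numeric(0)))
  reps <- do.call(rbind, lapply(summits, as.data.frame))
  res <- list()
  for (i in seq_len(nrow(reps))) {
    v <- reps$value[i]
    seed <- c(reps$row[i], reps$col[i])
    violated <- function(L) {
      reg <- flood_level(img, mask, seed, L)
      if (any(img[reg] > v)) return(TRUE)
      for (j in seq_len(nrow(reps))) {
        if (j == i || reps$value[j] != v) next
        if (reg[reps$row[j], reps$col[j]] &&
            (reps$row[j] < reps$row[i] ||
             (reps$row[j] == reps$row[i] && reps$col[j] < reps$col[i])))
          return(TRUE)
      }
      FALSE
    }
    region_all <- flood_level(img, mask, seed, -Inf)
    levels_desc <- sort(unique(img[region_all]), decreasing = TRUE)
    levels_desc <- levels_desc[levels_desc <= v]
    # violation is monotone: a lower flood level gives a superset region,
    # so binary-search the highest violating level (the saddle)
    if (!violated(levels_desc[length(levels_desc)])) {
      prom <- v - min(img[region_all])
    } else {
      lo <- 1                       # highest level, not violated (own summit)
      hi <- length(levels_desc)     # violated
      while (hi - lo > 1) {
        mid <- (lo + hi) %/% 2
        if (violated(levels_desc[mid])) hi <- mid else lo <- mid
      }
      prom <- v - levels_desc[hi]
    }
    if (prom > tolerance)
      res[[length(res) + 1]] <- data.frame(row = reps$row[i],
                                           col = reps$col[i], value = v,
                                           prominence = prom)
  }
  if (length(res) == 0)
    return(data.frame(row = numeric(0), col = numeric(0),
                      value = numeric(0), prominence = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$row, out$col), , drop = FALSE]
}

# Per-element volume bin assignment (closed-medium convention).
oracle_volume_fractions <- function(volumes, bounds = c(100, 1000)) {
  s <- 0; m <- 0; l <- 0
  for (v in volumes) {
    if (v < bounds[1]) s <- s + v
    else if (v > bounds[2]) l <- l + v
    else m <- m + v
  }
  100 * c(pct_small = s, pct_medium = m, pct_large = l) / sum(volumes)
}

# Match planted centres to segmented centroids (greedy nearest, one to
# one); returns logical vector over planted rows.
match_planted <- function(truth_rc, found_rc, max_dist = 4) {
  used <- rep(FALSE, nrow(found_rc))
  matched <- rep(FALSE, nrow(truth_rc))
  for (i in seq_len(nrow(truth_rc))) {
    if (nrow(found_rc) == 0) break
    d <- sqrt((found_rc[, 1] - truth_rc[i, 1])^2 +
              (found_rc[, 2] - truth_rc[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= max_dist) {
      used[j] <- TRUE
      matched[i] <- TRUE
    }
  }
  attr(matched, "n_unmatched_found") <- sum(!used)
  matched
}
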