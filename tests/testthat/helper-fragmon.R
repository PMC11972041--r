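# shared fixtures, built in code

random_line <- function() {
  line3(stats::runif(3, -50, 50), stats::rnorm(3))
}

# brute-force closest approach: coarse grid then local refinement with optim
brute_closest <- function(a, b, span = 500) {
  f <- function(p) {
    pa <- a$origin + p[1] * a$direction
    pb <- b$origin + p[2] * b$direction
    sum((pa - pb)^2)
  }
  g <- seq(-span, span, length.out = 81)
  best <- c(0, 0); bv <- Inf
  for (t1 in g) {
    pa <- a$origin + t1 * a$direction
    # optimal t2 given t1 is the projection onto b
    t2 <- sum((pa - b$origin) * b$direction)
    v <- f(c(t1, t2))
    if (v < bv) { bv <- v; best <- c(t1, t2) }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  pa <- a$origin + opt$par[1] * a$direction
  pb <- b$origin + opt$par[2] * b$direction
  list(midpoint = (pa + pb) / 2, distance = sqrt(opt$value))
}

# hit table builder
make_hits <- function(col, row, toa, energy, layer = "front", chip = 0L) {
  n <- length(col)
  data.frame(layer = rep_len(layer, n), chip = rep_len(chip, n),
             col = col, row = row, toa_ns = toa, energy_kev = energy)
}

# independent union-find clustering oracle: repeated merging to fixed point
oracle_cluster <- function(hits, window, eight = TRUE) {
  n <- nrow(hits)
  id <- seq_len(n)
  adjacent <- function(i, j) {
    dc <- abs(hits$col[i] - hits$col[j]); dr <- abs(hits$row[i] - hits$row[j])
    ok <- if (eight) dc <= 1 && dr <= 1 else (dc + dr) <= 1
    ok && abs(hits$toa_ns[i] - hits$toa_ns[j]) <= window
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (id[i] != id[j] && adjacent(i, j)) {
        id[id == max(id[i], id[j])] <- min(id[i], id[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(id, unique(id))
}

# exhaustive coincidence-matching oracle: all one-to-one partial matchings,
# maximize number of pairs, then minimize total |dt|
oracle_match <- function(ft, bt, window) {
  nf <- length(ft); nb <- length(bt)
  best <- list(n = -1, tot = Inf)
  recurse <- function(i, used_b, pairs) {
    if (i > nf) {
      n <- nrow(pairs)
      tot <- if (n > 0) sum(abs(ft[pairs$f] - bt[pairs$b])) else 0
      if (n > best$n || (n == best$n && tot < best$tot - 1e-12)) {
        best <<- list(n = n, tot = tot, pairs = pairs)
      }
      return(invisible())
    }
    recurse(i + 1, used_b, pairs)  # leave front i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && abs(ft[i] - bt[j]) <= window) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, rbind(pairs, data.frame(f = i, b = j)))
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, nb), data.frame(f = integer(), b = integer()))
  best
}

# tiny fast simulation settings for smoke tests
tiny_plan <- function(n_primaries = 500) {
  generate_plan(n_layers = 2, spots_per_layer = 6, n_primaries = n_primaries)
}
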