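# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the definition, sharing no code with the package.

# STTC by direct O(n*m) evaluation of the definition.
bruteSttc <- function(a, b, dt, duration) {
  if (!length(a) || !length(b)) return(0)
  near <- function(x, y) {
    mean(vapply(x, function(t) any(abs(t - y) <= dt), logical(1)))
  }
  tiled <- function(x) {
    # merge intervals by explicit scan
    lo <- pmax(0, x - dt); hi <- pmin(duration, x + dt)
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    tot <- 0; curLo <- lo[1]; curHi <- hi[1]
    for (i in seq_along(lo)[-1]) {
      if (lo[i] > curHi) {
        tot <- tot + (curHi - curLo)
        curLo <- lo[i]; curHi <- hi[i]
      } else {
        curHi <- max(curHi, hi[i])
      }
    }
    (tot + (curHi - curLo)) / duration
  }
  pa <- near(a, b); pb <- near(b, a)
  ta <- tiled(a); tb <- tiled(b)
  0.5 * ((pa - tb) / (1 - pa * tb) + (pb - ta) / (1 - pb * ta))
}

# DBSCAN cluster count by exhaustive reachability: core points from the
# neighbor counts, clusters as connected components of the core-core
# adjacency (within eps), border points attached but not bridging.
bruteDbscanCount <- function(d, eps, minSamples, selfCounting = FALSE) {
  n <- nrow(d)
  if (!n) return(0L)
  need <- if (selfCounting) minSamples - 1L else minSamples
  nbrCount <- vapply(seq_len(n), function(i) {
    sum(d[i, -i] <= eps)
  }, integer(1))
  core <- which(nbrCount >= need)
  if (!length(core)) return(0L)
  # connected components among core points via repeated matrix closure
  adj <- d[core, core, drop = FALSE] <= eps
  reach <- adj | diag(length(core)) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(length(core))
  k <- 0L
  for (i in seq_along(core)) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[which(reach[i, ])] <- k
    }
  }
  k
}

# Graph metrics from scratch: BFS shortest paths, triangle counting.
bruteGraphMetrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (u in nb) for (v in nb) if (u < v && adj[u, v] > 0) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1))
  bfs <- function(s) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in which(adj[u, ] > 0)) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    dist
  }
  effSum <- 0
  for (s in seq_len(n)) {
    dist <- bfs(s)
    for (t in seq_len(n)) {
      if (t != s && is.finite(dist[t])) effSum <- effSum + 1 / dist[t]
    }
  }
  list(nodeDegree = mean(deg), clusteringCoeff = mean(cc),
       efficiency = effSum / (n * (n - 1)))
}

# Davies-Bouldin from the definition, plain loops.
bruteDaviesBouldin <- function(x, labels) {
  ks <- sort(unique(labels))
  k <- length(ks)
  cents <- lapply(ks, function(kk) colMeans(x[labels == kk, , drop = FALSE]))
  sig <- vapply(seq_len(k), function(i) {
    pts <- x[labels == ks[i], , drop = FALSE]
    mean(apply(pts, 1, function(p) sqrt(sum((p - cents[[i]])^2))))
  }, numeric(1))
  total <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((cents[[i]] - cents[[j]])^2))
      r <- if (dij == 0) Inf else (sig[i] + sig[j]) / dij
      best <- max(best, r)
    }
    total <- total + best
  }
  total / k
}

# Poisson upper-tail probability by direct summation (for surprise checks).
brutePoissonTail <- function(nMin, lambda, nMax = 500L) {
  sum(stats::dpois(nMin:nMax, lambda))
}

# Random sorted spike train at a given rate.
randTrain <- function(rate, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}

# Assemble an MEARecording quickly from a list of trains.
quickRec <- function(spikes, duration = 300, div = 10, dish = "t") {
  MEARecording(dish, div, duration, spikes)
}
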