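## independent brute-force oracles, kept deliberately naive -----------------

## all-pairs shortest paths by repeated BFS over an adjacency list
oracle_distances <- function(mol) {
  hi <- which(mol$atoms$element != "H")
  pos <- match(seq_len(nrow(mol$atoms)), hi)
  n <- length(hi)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- pos[mol$bonds$a1[k]]; j <- pos[mol$bonds$a2[k]]
    if (!is.na(i) && !is.na(j)) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.infinite(d[s, u])) {
          d[s, u] <- d[s, v] + 1
          queue <- c(queue, u)
        }
      }
    }
  }
  d
}

## double-loop autocorrelation oracle
oracle_autocorrelation <- function(mol, w, lag, variant) {
  d <- oracle_distances(mol)
  n <- length(w)
  wbar <- mean(w)
  num <- 0; D <- 0; gnum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && d[i, j] == lag) {
      D <- D + 1
      num <- num + switch(variant,
                          ATS = , AATS = w[i] * w[j],
                          ATSC = , AATSC = , Moran =
                            (w[i] - wbar) * (w[j] - wbar))
      gnum <- gnum + (w[i] - w[j])^2
    }
  }
  if (D == 0) return(NA_real_)
  switch(variant,
    ATS = num, ATSC = num, AATS = num / D, AATSC = num / D,
    Moran = {
      s2 <- sum((w - wbar)^2) / n
      if (s2 <= 0) NA_real_ else (num / D) / s2
    },
    Geary = {
      s2 <- sum((w - wbar)^2) / (n - 1)
      if (s2 <= 0) NA_real_ else (gnum / (2 * D)) / s2
    })
}

## naive Burden matrix assembly
oracle_burden <- function(mol, wrel) {
  hi <- which(mol$atoms$element != "H")
  pos <- match(seq_len(nrow(mol$atoms)), hi)
  n <- length(hi)
  B <- matrix(0.001, n, n)
  diag(B) <- wrel
  deg <- integer(n)
  eb <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    i <- pos[mol$bonds$a1[k]]; j <- pos[mol$bonds$a2[k]]
    if (!is.na(i) && !is.na(j)) {
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      o <- mol$bonds$order[k]
      eb[[length(eb) + 1]] <- c(i, j, if (o == 4) 1.5 else o)
    }
  }
  for (e in eb) {
    v <- 0.1 * e[3]
    if (deg[e[1]] == 1 || deg[e[2]] == 1) v <- v + 0.01
    B[e[1], e[2]] <- v; B[e[2], e[1]] <- v
  }
  sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
}

## direct E-state evaluation
oracle_estate <- function(mol) {
  hi <- which(mol$atoms$element != "H")
  tab <- atom_property_table()
  nh <- integer(nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
    if (mol$atoms$element[a2] == "H") nh[a1] <- nh[a1] + 1L
    if (mol$atoms$element[a1] == "H") nh[a2] <- nh[a2] + 1L
  }
  d <- oracle_distances(mol)
  n <- length(hi)
  I <- numeric(n)
  for (p in seq_len(n)) {
    a <- hi[p]
    el <- mol$atoms$element[a]
    L <- tab[el, "quantum_l"]; zv <- tab[el, "n_valence"]
    delta <- sum(d[p, ] == 1)
    I[p] <- ((2 / L)^2 * (zv - nh[a]) + 1) / delta
  }
  S <- numeric(n)
  for (p in seq_len(n)) {
    S[p] <- I[p]
    for (q in seq_len(n)) {
      if (q != p) S[p] <- S[p] + (I[p] - I[q]) / (d[p, q] + 1)^2
    }
  }
  S
}

## exhaustive simple-path enumeration for the nitrogen weighted path
oracle_wtpt_n <- function(mol) {
  hi <- which(mol$atoms$element != "H")
  pos <- match(seq_len(nrow(mol$atoms)), hi)
  n <- length(hi)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- pos[mol$bonds$a1[k]]; j <- pos[mol$bonds$a2[k]]
    if (!is.na(i) && !is.na(j)) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  deg <- lengths(adj)
  total <- 0
  for (s in which(mol$atoms$element[hi] == "N")) {
    paths <- list(list(v = s, w = 1, seen = s))
    contrib <- 0
    while (length(paths) > 0) {
      cur <- paths[[1]]; paths <- paths[-1]
      for (u in adj[[cur$v]]) {
        if (!(u %in% cur$seen)) {
          w2 <- cur$w / sqrt(deg[cur$v] * deg[u])
          contrib <- contrib + w2
          paths[[length(paths) + 1]] <- list(v = u, w = w2,
                                             seen = c(cur$seen, u))
        }
      }
    }
    total <- total + 1 + contrib
  }
  total
}

## direct Eq.-style RDF evaluation, one pair at a time
oracle_rdf <- function(mol, n_bins = 128, r_max = 12.8, B = 100) {
  q <- mol$atoms$partial_charge
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  grid <- (r_max / n_bins) * seq_len(n_bins)
  out <- matrix(0, 3, n_bins,
                dimnames = list(c("a", "b", "c"), NULL))
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (q[i] == 0 || q[j] == 0) next
    s <- if (q[i] * q[j] < 0) "a" else if (q[i] > 0) "b" else "c"
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    out[s, ] <- out[s, ] + q[i] * q[j] * exp(-B * (grid - r)^2)
  }
  out
}

## naive Galvez charge index
oracle_tci <- function(mol, k) {
  d <- oracle_distances(mol)
  n <- nrow(d)
  A <- (d == 1) * 1
  Q <- ifelse(d == 0, 0, 1 / d^2)
  M <- A %*% Q
  CT <- M - t(M)
  tot <- 0; found <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] == k) { tot <- tot + abs(CT[i, j]); found <- TRUE }
  }
  if (!found) return(c(GGI = NA_real_, JGI = NA_real_))
  c(GGI = tot, JGI = tot / (n - 1))
}
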