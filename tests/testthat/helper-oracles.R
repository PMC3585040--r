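# shared oracles: a random timed merge tree and an exhaustive-enumeration
# likelihood (sums over all internal-node state assignments) used to check
# the pruning recursion

random_merge_tree <- function(ntip, max_branch = 5L) {
  nodes <- as.list(seq_len(ntip) - 1L)
  node_time <- rep(0L, ntip)
  ma <- mb <- integer(0)
  t <- 0L
  for (i in seq_len(ntip - 1L)) {
    t <- t + sample.int(max_branch, 1L)
    pick <- sample(length(nodes), 2L)
    ma <- c(ma, nodes[[pick[1]]]); mb <- c(mb, nodes[[pick[2]]])
    nodes[pick] <- NULL
    nodes[[length(nodes) + 1L]] <- ntip + i - 1L
    node_time <- c(node_time, t)
  }
  list(ntip = ntip, ma = ma, mb = mb, node_time = node_time)
}

# exhaustive likelihood over all internal-node states; root fixed at 0
brute_force_likelihood <- function(rec, states, M) {
  S <- nrow(M); w <- (S - 1L) %/% 2L
  nn <- length(rec$node_time)
  nint <- nn - rec$ntip
  pow <- list(diag(S))
  getp <- function(t) {
    while (length(pow) <= t) pow[[length(pow) + 1L]] <<- pow[[length(pow)]] %*% M
    pow[[t + 1L]]
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), nint)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    asg <- c(rep(NA_integer_, rec$ntip), grid[r, ])
    if (asg[nn] != w + 1L) next # root state fixed at offset 0
    p <- 1
    for (ci in seq_along(rec$ma)) {
      id <- rec$ntip + ci
      for (kid in c(rec$ma[ci] + 1L, rec$mb[ci] + 1L)) {
        t <- rec$node_time[id] - rec$node_time[kid]
        Mt <- getp(t)
        p <- p * if (kid <= rec$ntip) {
          s <- states[kid]
          if (is.na(s)) 1 else Mt[asg[id], s + w + 1L]
        } else Mt[asg[id], asg[kid]]
      }
    }
    tot <- tot + p
  }
  tot
}

rec_to_genealogy <- function(rec) {
  nmerge <- length(rec$ma)
  ntip <- rec$ntip
  apeid <- c(seq_len(ntip), ntip + rev(seq_len(nmerge)))
  edge <- matrix(0L, 2L * nmerge, 2L)
  elen <- numeric(2L * nmerge)
  for (ci in seq_len(nmerge)) {
    kids <- c(rec$ma[ci], rec$mb[ci]) + 1L
    for (s in 1:2) {
      edge[2L * (ci - 1L) + s, ] <- c(apeid[ntip + ci], apeid[kids[s]])
      elen[2L * (ci - 1L) + s] <- rec$node_time[ntip + ci] - rec$node_time[kids[s]]
    }
  }
  nt <- integer(ntip + nmerge)
  nt[apeid] <- rec$node_time
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("cell", seq_len(ntip)),
                        Nnode = nmerge),
                   class = c("crypt_genealogy", "phylo"), order = "cladewise")
  attr(phy, "node_time") <- nt
  attr(phy, "node_deme") <- rep(1L, ntip + nmerge)
  phy
}
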