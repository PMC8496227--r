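# Shared fixtures: tiny trees, a minimal two-chain coordinate file, and
# independent oracles (quadratic local alignment via Biostrings, brute-force
# NG86 path enumeration) used across the suite.

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# independent Smith-Waterman oracle (Biostrings dynamic programme), matching
# the scanner's scoring: +1/-2, gap of length L costs 4 + L
swOracle <- function(q, t) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(t), type = "local",
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 1))
}

# brute-force NG86 pair counts: enumerate all orderings of the differing
# positions, discard paths through stops (fall back to all paths)
pairOracle <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  d <- which(s1 != s2)
  if (length(d) == 0) return(c(nd = 0, sd = 0))
  perms <- function(x) if (length(x) == 1) list(x) else
    do.call(c, lapply(seq_along(x), function(i)
      lapply(perms(x[-i]), function(p) c(x[i], p))))
  score <- function(ord, allowStops) {
    cur <- s1; nd <- 0; sd <- 0
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- s2[pos]
      if (!allowStops && gc[paste(nxt, collapse = "")] == "*") return(NULL)
      if (gc[paste(cur, collapse = "")] != gc[paste(nxt, collapse = "")])
        nd <- nd + 1 else sd <- sd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd)
  }
  res <- Filter(Negate(is.null), lapply(perms(d), score, allowStops = FALSE))
  if (!length(res)) res <- lapply(perms(d), score, allowStops = TRUE)
  colMeans(do.call(rbind, res))
}

# exhaustive-state codon likelihood oracle for trees read by ape; single
# omega, uniform or supplied frequencies
exhaustiveLoglik <- function(aln, tree, kappa, omega, pi) {
  type <- retroforge:::.codonType()
  mu <- retroforge:::.rfMeanRate(type, pi, kappa, omega)
  po <- ape::reorder.phylo(tree, "postorder")
  P <- lapply(po$edge.length, function(t)
    retroforge:::.rfPmat(type, pi, kappa, omega, t / mu))
  m <- codonMatrix(aln)
  ci <- retroforge:::.rf$codonIndex
  ntip <- length(po$tip.label)
  nnode <- max(po$edge)
  S <- ncol(m)
  total <- 0
  for (s in seq_len(S)) {
    states <- lapply(seq_len(nnode), function(v)
      if (v <= ntip) ci[[m[po$tip.label[v], s]]] else 1:61)
    grid <- expand.grid(states[(ntip + 1):nnode])
    lik <- 0
    root <- po$edge[nrow(po$edge), 1]
    for (g in seq_len(nrow(grid))) {
      assign <- integer(nnode)
      assign[seq_len(ntip)] <- vapply(seq_len(ntip), function(v)
        states[[v]], numeric(1))
      assign[(ntip + 1):nnode] <- as.integer(grid[g, ])
      p <- pi[assign[root]]
      for (e in seq_len(nrow(po$edge))) {
        p <- p * P[[e]][assign[po$edge[e, 1]], assign[po$edge[e, 2]]]
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# minimal fixed-column ATOM coordinate file with two chains
writeToyStructure <- function(path, chainA, chainB) {
  fmtAtom <- function(serial, name, resname, chain, resno, x, y, z) {
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, sprintf(" %-3s", name), resname, chain, resno, x, y, z)
  }
  lines <- character(0)
  serial <- 1
  add <- function(df, chain) {
    for (i in seq_len(nrow(df))) {
      lines <<- c(lines, fmtAtom(serial, df$elety[i], df$resid[i], chain,
                                 df$resno[i], df$x[i], df$y[i], df$z[i]))
      serial <<- serial + 1
    }
  }
  add(chainA, "A")
  add(chainB, "B")
  writeLines(c(lines, "END"), path)
  path
}

toyChain <- function(n, xoff = 0, zoff = 0) {
  data.frame(resno = seq_len(n), resid = "ALA", elety = "CA",
             x = seq_len(n) * 3 + xoff, y = 0, z = zoff,
             stringsAsFactors = FALSE)
}
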