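# Genetic-code tables shared by the NG86 counters, the GY94 machinery and the
# simulators. Built once from the standard nuclear code shipped with
# Biostrings and cached in the package environment.

.NUC <- c("T", "C", "A", "G")

.codonTables <- function() {
  if (!is.null(.rf$codons)) return(invisible(NULL))
  gc <- Biostrings::GENETIC_CODE
  all64 <- names(gc)
  sense <- all64[gc != "*"]
  stopifnot(length(sense) == 61L)
  .rf$codons <- sense
  .rf$stops <- all64[gc == "*"]
  .rf$aa <- gc[sense]
  .rf$codonIndex <- setNames(seq_along(sense), sense)

  # 61 x 61 single-nt neighbour classification:
  # 0 none, 1 syn tv, 2 syn ts, 3 nonsyn tv, 4 nonsyn ts
  isTs <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  n <- length(sense)
  type <- matrix(0L, n, n, dimnames = list(sense, sense))
  sp <- strsplit(sense, "")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(sp[[i]] != sp[[j]])
    if (length(d) != 1L) next
    ts <- isTs(sp[[i]][d], sp[[j]][d])
    syn <- .rf$aa[i] == .rf$aa[j]
    type[i, j] <- if (syn) (if (ts) 2L else 1L) else (if (ts) 4L else 3L)
  }
  .rf$type <- type

  # NG86 synonymous site fraction per codon: at each position, the fraction of
  # sense single-nt changes that are synonymous (stop-producing changes are
  # excluded and each position contributes one site, so N + S = 3 per codon).
  sfrac <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (pos in 1:3) {
      alts <- .NUC[.NUC != sp[[i]][pos]]
      cods <- vapply(alts, function(a) {
        x <- sp[[i]]; x[pos] <- a; paste(x, collapse = "")
      }, character(1))
      senseAlts <- cods[!cods %in% .rf$stops]
      if (length(senseAlts) == 0L) next
      s <- s + mean(gc[senseAlts] == .rf$aa[i])
    }
    sfrac[i] <- s
  }
  .rf$sSites <- setNames(sfrac, sense)
  invisible(NULL)
}

.codons <- function() { .codonTables(); .rf$codons }
.codonType <- function() { .codonTables(); .rf$type }
.codonAA <- function() { .codonTables(); .rf$aa }

# Average synonymous/nonsynonymous difference counts between two codons over
# all minimal substitution paths; paths through stop codons are discarded
# (unless every path is blocked, in which case all paths are used).
.pairDiffs <- function(c1, c2) {
  .codonTables()
  if (c1 == c2) return(c(nd = 0, sd = 0))
  key <- paste0(c1, c2)
  if (is.null(.rf$pairCache)) .rf$pairCache <- new.env(parent = emptyenv())
  hit <- .rf$pairCache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- Biostrings::GENETIC_CODE
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  d <- which(s1 != s2)
  paths <- if (length(d) == 1L) list(d) else
    lapply(asplit(.permutations(d), 1), as.integer)
  score <- function(ord, allowStops) {
    cur <- s1; nd <- 0; sdf <- 0
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- s2[pos]
      cod1 <- paste(cur, collapse = ""); cod2 <- paste(nxt, collapse = "")
      if (!allowStops && gc[cod2] == "*") return(NULL)
      if (gc[cod1] == "*" || gc[cod2] == "*" || gc[cod1] != gc[cod2])
        nd <- nd + 1 else sdf <- sdf + 1
      cur <- nxt
    }
    c(nd = nd, sd = sdf)
  }
  res <- Filter(Negate(is.null), lapply(paths, score, allowStops = FALSE))
  if (length(res) == 0L) res <- lapply(paths, score, allowStops = TRUE)
  out <- colMeans(do.call(rbind, res))
  .rf$pairCache[[key]] <- out
  out
}

.permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], .permutations(x[-i])))
  out
}

.splitCodons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
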