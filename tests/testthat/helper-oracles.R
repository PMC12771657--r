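# independent brute-force oracles used to validate the scanners and NG86

.ACGT <- c("A", "C", "G", "T")

# every maximal perfect tandem run, by direct per-position unit counting
oracleSSRs <- function(seq, thresholds = c(10L, 6L, 5L, 4L, 3L, 3L)) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  recs <- list()
  for (u in 1:6) {
    for (i in seq_len(n - u)) {
      unit <- ch[i:(i + u - 1)]
      if (any(!unit %in% .ACGT)) next
      # leftmost phase of its maximal run
      if (i > 1 && ch[i - 1] %in% .ACGT && ch[i - 1] == ch[i - 1 + u]) next
      k <- 1L
      while (i + (k + 1L) * u - 1L <= n &&
             all(ch[(i + k * u):(i + (k + 1L) * u - 1L)] == unit))
        k <- k + 1L
      if (k < thresholds[u]) next
      # primitive motif only
      primitive <- TRUE
      for (d in seq_len(u - 1)) {
        if (u %% d == 0 &&
            all(unit == rep(unit[1:d], length.out = u))) {
          primitive <- FALSE; break
        }
      }
      if (!primitive) next
      recs[[length(recs) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + u * k,
        motif = paste(unit, collapse = ""), unit_len = u, repeats = k)
    }
  }
  if (!length(recs))
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), unit_len = integer(),
                      repeats = integer()))
  out <- do.call(rbind, recs)
  out[order(out$start, out$unit_len), ]
}

# all maximal exact matches between strings a and b by diagonal run-length
# scanning (0-based starts)
oracleMems <- function(a, b, min_len) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  na <- length(A); nb <- length(B)
  out <- list()
  for (d in (-(na - 1)):(nb - 1)) {
    i0 <- max(1L, 1L - d); i1 <- min(na, nb - d)
    if (i1 - i0 + 1L < min_len) next
    idx <- i0:i1
    eq <- A[idx] == B[idx + d] & A[idx] %in% .ACGT & B[idx + d] %in% .ACGT
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= min_len)) {
      len <- r$lengths[k]
      st <- idx[ends[k] - len + 1L]
      out[[length(out) + 1L]] <- c(i = st - 1L, j = st - 1L + d, len = len)
    }
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), len = integer()))
  as.data.frame(do.call(rbind, out))
}

# brute-force long-repeat records (same output contract as findLongRepeats)
oracleLongRepeats <- function(seq, min_len,
                              types = c("F", "P", "R", "C")) {
  n <- nchar(seq)
  d <- Biostrings::DNAString(seq)
  tr <- list(F = seq,
             P = as.character(Biostrings::reverseComplement(d)),
             R = as.character(Biostrings::reverse(d)),
             C = as.character(Biostrings::complement(d)))
  out <- list()
  for (ty in types) {
    mem <- oracleMems(seq, tr[[ty]], min_len)
    if (!nrow(mem)) next
    if (ty %in% c("P", "R")) {
      p2 <- n - mem$j - mem$len
      keep <- mem$i != p2
      df <- data.frame(pos1 = pmin(mem$i, p2)[keep],
                       pos2 = pmax(mem$i, p2)[keep],
                       length = mem$len[keep])
      self <- which(!keep)
      if (length(self)) {   # contiguous palindrome: report the two halves
        h <- mem$len[self] %/% 2L
        df <- rbind(df, data.frame(
          pos1 = mem$i[self], pos2 = mem$i[self] + mem$len[self] - h,
          length = h))
        df <- df[df$length >= min_len, , drop = FALSE]
      }
    } else {
      keep <- mem$i != mem$j
      df <- data.frame(pos1 = pmin(mem$i, mem$j)[keep],
                       pos2 = pmax(mem$i, mem$j)[keep],
                       length = mem$len[keep])
    }
    df <- unique(df)
    if (nrow(df)) { df$rtype <- ty; out[[ty]] <- df }
  }
  if (!length(out))
    return(data.frame(rtype = character(), length = integer(),
                      pos1 = integer(), pos2 = integer()))
  res <- do.call(rbind, out)[, c("rtype", "length", "pos1", "pos2")]
  res[order(res$rtype, res$pos1, res$pos2), ]
}

sortedRepeatKey <- function(df)
  sort(paste(df$rtype, df$length, df$pos1, df$pos2))

# direct (definition-level) alignment column classification
oracleClassifySite <- function(column) {
  obs <- column[column %in% .ACGT]
  if (length(obs) < 2) return("excluded")
  tab <- table(obs)
  if (length(tab) == 1) return("invariant")
  if (sum(tab >= 2) >= 2) return("parsimony_informative")
  if (length(tab) == 2 && sum(tab == 1) == 1) return("singleton")
  "other_variable"
}

# direct per-window Pi: mean over pairs of diff/valid
oraclePi <- function(aln, start, end) {
  sub <- aln[, (start + 1):end, drop = FALSE]
  n <- nrow(sub)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- sub[i, ] %in% .ACGT & sub[j, ] %in% .ACGT
      if (!any(ok)) next
      vals <- c(vals, sum(sub[i, ok] != sub[j, ok]) / sum(ok))
    }
  }
  if (!length(vals)) 0 else mean(vals)
}

# ---- NG86 oracle: recursive pathway enumeration -----------------------------

.oracleCode <- Biostrings::getGeneticCode("11")

oracleCodonSiteCounts <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(.ACGT, substring(codon, pos, pos))
    neigh <- vapply(alts, function(b) {
      x <- codon; substring(x, pos, pos) <- b; x
    }, character(1))
    neigh <- neigh[.oracleCode[neigh] != "*"]
    if (length(neigh))
      s <- s + sum(.oracleCode[neigh] == .oracleCode[codon]) / length(neigh)
  }
  c(syn = s, nonsyn = 3 - s)
}

# enumerate all substitution orders recursively; drop pathways through stops
oraclePathCounts <- function(a, b) {
  dpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(0, 0)))
    res <- list()
    for (p in remaining) {
      nxt <- cur
      substring(nxt, p, p) <- substring(b, p, p)
      if (.oracleCode[nxt] == "*") next
      step <- if (.oracleCode[nxt] == .oracleCode[cur]) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, setdiff(remaining, p)))
        res[[length(res) + 1L]] <- step + tail
    }
    res
  }
  paths <- walk(a, dpos)
  if (!length(paths)) return(c(sd = NA_real_, nd = NA_real_))
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

oracleNg86 <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, function(c) oracleCodonSiteCounts(c)[["syn"]],
                   1)) +
        sum(vapply(codons_b, function(c) oracleCodonSiteCounts(c)[["syn"]],
                   1))) / 2
  N <- 3 * length(codons_a) - S
  sd <- 0; nd <- 0
  for (k in seq_along(codons_a)) {
    pc <- oraclePathCounts(codons_a[k], codons_b[k])
    sd <- sd + pc[["sd"]]; nd <- nd + pc[["nd"]]
  }
  list(S = S, N = N, Sd = sd, Nd = nd)
}

randomCDS <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  mid <- character(n_codons - 2)
  for (i in seq_along(mid)) {
    x <- "TAA"
    while (x %in% stops) x <- paste(sample(.ACGT, 3, TRUE), collapse = "")
    mid[i] <- x
  }
  paste0("ATG", paste(mid, collapse = ""), "TAA")
}
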