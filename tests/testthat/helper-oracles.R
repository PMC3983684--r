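# Brute-force oracles, deliberately independent of the implementation
# paths they check.

# half-open overlap with strand relation, by direct case analysis
oracle_overlap <- function(a, b, mode) {
  if (a$chrom != b$chrom) return(FALSE)
  inter <- max(a$start, b$start) < min(a$end, b$end)
  if (!inter) return(FALSE)
  if (mode == "any_strand") return(TRUE)
  if (a$strand == "." || b$strand == ".") return(FALSE)
  if (mode == "same_strand") return(a$strand == b$strand)
  a$strand != b$strand
}

# all-pairs nearest TSS per peak, with the abundance/id tie rule
oracle_nearest <- function(peaks, tx, abundance = NULL) {
  ab <- function(id) {
    if (is.null(abundance) || is.na(abundance[id])) 0 else abundance[[id]]
  }
  out <- list()
  for (j in seq_len(nrow(peaks))) {
    best <- NULL
    for (i in seq_len(nrow(tx))) {
      if (tx$chrom[i] != peaks$chrom[j]) next
      d <- abs(tx$tss[i] - peaks$summit[j])
      if (is.null(best) || d < best$d ||
          (d == best$d && (ab(tx$id[i]) > best$ab ||
                           (ab(tx$id[i]) == best$ab &&
                            tx$id[i] < best$id)))) {
        best <- list(d = d, id = tx$id[i], ab = ab(tx$id[i]))
      }
    }
    out[[j]] <- if (is.null(best)) NULL else
      data.frame(peak_id = peaks$id[j], transcript_id = best$id,
                 abs_distance = best$d)
  }
  do.call(rbind, out)
}

# Spearman rho from first principles: average ranks + explicit
# product-moment formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# longest ORF by scanning every ATG in every forward frame
oracle_orf_score <- function(s) {
  s <- toupper(s)
  L <- nchar(s)
  best <- 0
  for (start in 1:(L - 2)) {
    if (substr(s, start, start + 2) != "ATG") next
    pos <- start + 3
    while (pos + 2 <= L) {
      cod <- substr(s, pos, pos + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, pos + 2 - start + 1)
        break
      }
      pos <- pos + 3
    }
  }
  best / L
}

# Mann-Whitney U by counting pairs
oracle_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# exact two-sided rank-sum p-value by enumerating all group assignments
oracle_ranksum_exact_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  obs <- oracle_u_stat(x, y)
  mu <- n1 * length(y) / 2
  combs <- utils::combn(n, n1)
  stat <- apply(combs, 2, function(idx)
    oracle_u_stat(pooled[idx], pooled[-idx]))
  mean(abs(stat - mu) >= abs(obs - mu))
}

# GSEA running sum written as an explicit loop
oracle_gsea_es <- function(ids, scores, set, p) {
  nh <- sum(ids %in% set)
  nr <- sum(abs(scores[ids %in% set])^p)
  run <- 0; best <- 0
  for (i in seq_along(ids)) {
    if (ids[i] %in% set) {
      run <- run + (if (nr > 0) abs(scores[i])^p / nr else 1 / nh)
    } else {
      run <- run - 1 / (length(ids) - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}
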