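#' Count k-mers of a sequence collection
#'
#' Overlapping k-mers are counted on the given strand in lexicographic
#' order over `{A, C, G, T}` (all `4^k` k-mers, zeros included); windows
#' containing non-ACGT symbols are skipped. With `canonical = TRUE` each
#' k-mer is pooled with its reverse complement.
#'
#' @param seqs Character vector of DNA strings (a read tibble's `bases`
#'   column, or a genome sequence).
#' @param k K-mer size in `[2, 8]` (default 6, the hexamer profile).
#' @param label Profile label used in clustering and reports.
#' @param canonical Pool each k-mer with its reverse complement.
#' @return An object of class `kmer_profile`: `label`, `k`, `counts`
#'   (named integer vector of length `4^k`), `total`.
#' @export
#' @examples
#' count_kmers("ACGTAC", k = 6, label = "toy")
count_kmers <- function(seqs, k = 6, label = "profile", canonical = FALSE) {
  stopifnot(k >= 2, k <= 8)
  seqs <- seqs[nchar(seqs) > 0L]
  if (length(seqs) == 0L) {
    nm <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    counts <- stats::setNames(integer(4^k), nm)
  } else {
    counts <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = k,
      simplify.as = "collapsed")
  }
  if (canonical) {
    rc <- reverse_complement(names(counts))
    counts <- counts + counts[rc]
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(label = label, k = as.integer(k),
                 counts = counts, total = sum(counts)),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("<kmer_profile> %s: k=%d, %s k-mer occurrences, %d/%d distinct\n",
              x$label, x$k, format(x$total, big.mark = ","),
              sum(x$counts > 0), length(x$counts)))
  invisible(x)
}

#' @export
as_tibble.kmer_profile <- function(x, ...) {
  tibble::tibble(kmer = names(x$counts), count = as.integer(x$counts),
                 rel_abundance = if (x$total > 0) x$counts / x$total else 0)
}

#' Relative k-mer abundances of a profile
#'
#' @param profile A [count_kmers()] profile.
#' @return Named numeric vector summing to 1 (when `total > 0`).
#' @export
rel_abundance <- function(profile) {
  stopifnot(inherits(profile, "kmer_profile"))
  if (profile$total == 0) return(profile$counts * 0)
  profile$counts / profile$total
}

#' Sum two k-mer profiles
#' @param e1,e2 `kmer_profile` objects with equal `k`.
#' @return Their componentwise sum.
#' @export
`+.kmer_profile` <- function(e1, e2) {
  stopifnot(e1$k == e2$k)
  structure(list(label = paste(e1$label, e2$label, sep = "+"), k = e1$k,
                 counts = e1$counts + e2$counts,
                 total = e1$total + e2$total),
            class = "kmer_profile")
}

#' K-mer profile of a genome, counted on both strands
#'
#' Sequencing reads sample both strands of a genome, so a genome profile
#' meant for comparison against read-derived profiles must pool the
#' forward sequence with its reverse complement; counting one strand only
#' would understate the read profile's expected composition and, for
#' near-random sequence, halve its variance.
#'
#' @param g A [genome()].
#' @param k K-mer size.
#' @param label Profile label (defaults to the genome id).
#' @return A `kmer_profile`.
#' @export
genome_profile <- function(g, k = 6, label = g$id) {
  stopifnot(inherits(g, "genome"))
  count_kmers(c(g$sequence, reverse_complement(g$sequence)), k = k,
              label = label)
}

#' Resample a k-mer profile to a common sequencing depth
#'
#' Draws `depth` k-mer occurrences with replacement (multinomial) from the
#' profile's relative abundances. Profiles built from different amounts of
#' sequence have count lattices and sampling variances that differ purely
#' with depth; resampling every profile to one common depth puts them on
#' an equal footing before their abundance distributions are compared --
#' the k-mer analogue of rarefying community counts, with replacement so
#' the resampled noise is identical across profiles.
#'
#' @param profile A [count_kmers()] profile with `total > 0`.
#' @param depth Number of k-mer occurrences to draw.
#' @param seed Integer seed.
#' @return A `kmer_profile` with `total = depth`.
#' @export
resample_profile <- function(profile, depth, seed = 1L) {
  stopifnot(inherits(profile, "kmer_profile"), profile$total > 0,
            depth >= 1)
  counts <- withr::with_seed(seed, {
    stats::rmultinom(1, depth, rel_abundance(profile))[, 1]
  })
  structure(list(label = profile$label, k = profile$k,
                 counts = stats::setNames(as.integer(counts),
                                          names(profile$counts)),
                 total = as.integer(depth)),
            class = "kmer_profile")
}

#' Method-of-moments gamma fit to k-mer relative abundances
#'
#' Genome-derived k-mer abundance distributions are well described by a
#' gamma law; the fit is by moments on the `4^k` relative abundances:
#' `shape = mean^2 / var`, `scale = var / mean`.
#'
#' @param profile A [count_kmers()] profile with >= 10 nonzero counts.
#' @return One-row tibble: `shape`, `scale`, `mean`, `var`.
#' @export
fit_gamma <- function(profile) {
  stopifnot(inherits(profile, "kmer_profile"))
  if (sum(profile$counts > 0) < 10) {
    stop("gamma fit requires at least 10 nonzero k-mer counts",
         call. = FALSE)
  }
  x <- rel_abundance(profile)
  m <- mean(x)
  v <- stats::var(x)
  if (v == 0) stop("degenerate profile: zero variance", call. = FALSE)
  tibble::tibble(shape = m^2 / v, scale = v / m, mean = m, var = v)
}

#' Correlation dissimilarity between two k-mer profiles
#'
#' `1 - Pearson correlation` of the relative-abundance vectors, in
#' `[0, 2]`; 0 iff the relative abundances are proportional.
#'
#' @param a,b [count_kmers()] profiles with equal `k`.
#' @return A single dissimilarity.
#' @export
profile_distance <- function(a, b) {
  stopifnot(inherits(a, "kmer_profile"), inherits(b, "kmer_profile"),
            a$k == b$k)
  ra <- rel_abundance(a)
  rb <- rel_abundance(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop("zero-variance profile has no defined correlation distance",
         call. = FALSE)
  }
  1 - stats::cor(ra, rb)
}

profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 2,
            all(vapply(profiles, inherits, TRUE, "kmer_profile")))
  ks <- vapply(profiles, `[[`, 0L, "k")
  if (length(unique(ks)) != 1L) stop("profiles must share k", call. = FALSE)
  m <- do.call(rbind, lapply(profiles, `[[`, "counts"))
  rownames(m) <- vapply(profiles, `[[`, "", "label")
  if (anyDuplicated(rownames(m))) {
    stop("profile labels must be unique", call. = FALSE)
  }
  m
}

cor_dist <- function(rel) stats::as.dist(1 - stats::cor(t(rel)))

## leaf bipartitions of an hclust tree as canonical strings
hclust_bipartitions <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    mem <- unlist(lapply(hc$merge[i, ], function(j) {
      if (j < 0) -j else sets[[j]]
    }))
    sets[[i]] <- sort(mem)
  }
  vapply(sets, function(s) paste(sort(labs[s]), collapse = "|"), "")
}

#' Average-linkage clustering of k-mer profiles with bootstrap support
#'
#' Profiles are clustered by average linkage on the correlation
#' dissimilarity ([profile_distance()]). Support values are ordinary
#' bootstrap percentages: the `4^k` k-mer columns are resampled with
#' replacement `n_boot` times, the tree is rebuilt, and each internal
#' edge's support is the percentage of replicate trees containing the same
#' leaf bipartition. With `n_boot = 0` the plain dendrogram is returned
#' with supports absent.
#'
#' @param profiles List of >= 3 [count_kmers()] profiles sharing `k`.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return An object of class `boot_hclust`: the `hclust` tree, a
#'   `support` tibble (one row per internal node: `node`, `members`,
#'   `support`), `n_boot`, and the profile matrix.
#' @export
hclust_bootstrap <- function(profiles, n_boot = 1000, seed = 1L) {
  m <- profile_matrix(profiles)
  if (nrow(m) < 3) stop("at least 3 profiles required", call. = FALSE)
  rel <- m / rowSums(m)
  hc <- stats::hclust(cor_dist(rel), method = "average")
  parts <- hclust_bipartitions(hc)
  support <- rep(NA_real_, length(parts))
  if (n_boot > 0) {
    hits <- stats::setNames(numeric(length(parts)), parts)
    withr::with_seed(seed, {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(ncol(m), replace = TRUE)
        mb <- m[, idx, drop = FALSE]
        relb <- mb / pmax(rowSums(mb), 1)
        hb <- stats::hclust(cor_dist(relb), method = "average")
        pb <- hclust_bipartitions(hb)
        seen <- parts %in% pb
        hits[seen] <- hits[seen] + 1
      }
    })
    support <- 100 * unname(hits) / n_boot
  }
  structure(list(
    hclust = hc,
    support = tibble::tibble(node = seq_along(parts), members = parts,
                             support = support),
    n_boot = n_boot, matrix = m
  ), class = "boot_hclust")
}

#' @export
print.boot_hclust <- function(x, ...) {
  cat(sprintf("<boot_hclust> %d profiles, %d bootstrap replicates\n",
              length(x$hclust$labels), x$n_boot))
  print(x$support)
  invisible(x)
}

#' Bootstrap support of the clade joining a set of leaves
#'
#' @param x A [hclust_bootstrap()] result.
#' @param leaves Character vector of leaf labels.
#' @return Support percentage of the bipartition `{leaves}` vs the rest,
#'   or `NA` if that clade is not in the consensus tree.
#' @export
clade_support <- function(x, leaves) {
  stopifnot(inherits(x, "boot_hclust"))
  key <- paste(sort(leaves), collapse = "|")
  hit <- match(key, x$support$members)
  if (is.na(hit)) NA_real_ else x$support$support[hit]
}

#' Export a bootstrapped dendrogram as Newick
#'
#' Internal-node bootstrap supports become node labels.
#'
#' @param x A [hclust_bootstrap()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "boot_hclust"))
  phy <- ape::as.phylo(x$hclust)
  ## ape node numbering: internal node i corresponds to hclust merge rows
  ## via match on clade membership
  parts <- x$support$members
  phy_parts <- vapply(ape::subtrees(phy), function(s) {
    paste(sort(s$tip.label), collapse = "|")
  }, "")
  node_lab <- x$support$support[match(phy_parts, parts)]
  phy$node.label <- ifelse(is.na(node_lab), "", format(node_lab))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Correspondence analysis of k-mer profiles
#'
#' Standard correspondence analysis of the profiles-by-k-mers count table:
#' the correspondence matrix `P = X / n` is centred and standardised to
#' `S = Dr^(-1/2) (P - r c') Dc^(-1/2)`, decomposed by SVD, and row/column
#' principal coordinates are returned. All-zero columns are pruned and
#' reported. Total inertia equals the table's chi-square statistic divided
#' by its grand total.
#'
#' @param profiles List of >= 2 [count_kmers()] profiles sharing `k`.
#' @param dims Number of principal dimensions to keep (capped by the
#'   table's rank).
#' @return An object of class `ca_result`: `row_coords`, `col_coords`
#'   (tibbles), `inertias`, `total_inertia`, `dims`, `pruned_columns`,
#'   `rank_deficient`.
#' @export
correspondence_analysis <- function(profiles, dims = 2) {
  m <- profile_matrix(profiles)
  zero_col <- colSums(m) == 0
  pruned <- colnames(m)[zero_col]
  m <- m[, !zero_col, drop = FALSE]
  if (any(rowSums(m) == 0)) {
    stop("all-zero profile row after pruning", call. = FALSE)
  }
  n <- sum(m)
  P <- m / n
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  pos <- sv$d > 1e-12 & sv$d > max(sv$d) * 1e-10
  max_dims <- sum(pos)
  rank_deficient <- dims > max_dims
  d_use <- min(dims, max_dims)
  if (d_use < 1) {
    ## identical rows: zero inertia, no principal dimensions
    return(structure(list(
      row_coords = tibble::tibble(label = rownames(m), mass = unname(r)),
      col_coords = tibble::tibble(kmer = colnames(m), mass = unname(cc)),
      inertias = numeric(0), total_inertia = 0, dims = 0L,
      pruned_columns = pruned, rank_deficient = TRUE
    ), class = "ca_result"))
  }
  idx <- seq_len(d_use)
  rowc <- diag(1 / sqrt(r)) %*% sv$u[, idx, drop = FALSE] %*%
    diag(sv$d[idx], nrow = d_use)
  colc <- diag(1 / sqrt(cc)) %*% sv$v[, idx, drop = FALSE] %*%
    diag(sv$d[idx], nrow = d_use)
  dimnames(rowc) <- list(rownames(m), paste0("dim", idx))
  dimnames(colc) <- list(colnames(m), paste0("dim", idx))
  structure(list(
    row_coords = dplyr::bind_cols(tibble::tibble(label = rownames(m),
                                                 mass = unname(r)),
                                  tibble::as_tibble(rowc)),
    col_coords = dplyr::bind_cols(tibble::tibble(kmer = colnames(m),
                                                 mass = unname(cc)),
                                  tibble::as_tibble(colc)),
    inertias = sv$d[pos]^2,
    total_inertia = sum(sv$d^2),
    dims = as.integer(d_use),
    pruned_columns = pruned,
    rank_deficient = rank_deficient
  ), class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("<ca_result> %d rows, %d dims kept, total inertia %.6g\n",
              nrow(x$row_coords), x$dims, x$total_inertia))
  if (x$rank_deficient) cat("  note: fewer dimensions than requested (rank)\n")
  invisible(x)
}

#' Tidy correspondence-analysis coordinates
#'
#' @param x A `ca_result`.
#' @param which `"rows"` or `"columns"`.
#' @param ... Unused.
#' @return `tidy()` returns the coordinate tibble; `glance()` a one-row
#'   tibble with inertia summaries.
#' @export
tidy.ca_result <- function(x, which = c("rows", "columns"), ...) {
  which <- match.arg(which)
  if (which == "rows") x$row_coords else x$col_coords
}

#' @rdname tidy.ca_result
#' @export
glance.ca_result <- function(x, ...) {
  tibble::tibble(dims = x$dims, total_inertia = x$total_inertia,
                 inertia_dim1 = x$inertias[1],
                 inertia_dim2 = if (length(x$inertias) >= 2) x$inertias[2] else NA_real_,
                 n_pruned_columns = length(x$pruned_columns),
                 rank_deficient = x$rank_deficient)
}

#' Attribute unassigned reads to a source genome by hexamer composition
#'
#' Builds k-mer profiles for the unassigned read set, each candidate
#' genome and the artificial null genome; compares the unassigned
#' relative-abundance distribution against the null and each candidate
#' with [cvm_gof()]; and clusters all profiles with [hclust_bootstrap()],
#' naming the candidate whose profile the unassigned set joins and the
#' bootstrap support of that pairing. With a single candidate the
#' clustering is skipped (with an explicit notice) and the CvM results are
#' still emitted.
#'
#' @param unassigned_reads Read tibble of unassigned reads.
#' @param candidate_genomes List of candidate [genome()] objects.
#' @param null_genome The artificial null [genome()].
#' @param k K-mer size (default 6).
#' @param n_boot Bootstrap replicates for the clustering.
#' @param n_perm Permutations for the CvM tests.
#' @param seed Integer seed.
#' @return A list of class `attribution_report`: `comparisons` (tibble:
#'   one row per candidate plus the null, with CvM statistic/p and profile
#'   distance), `best_candidate`, `best_support` (bootstrap percentage of
#'   the unassigned/best-candidate pairing, `NA` when clustering was
#'   skipped), `clustering` (a `boot_hclust` or `NULL`), `notice`.
#' @export
attribute_unassigned <- function(unassigned_reads, candidate_genomes,
                                 null_genome, k = 6, n_boot = 1000,
                                 n_perm = 999, seed = 1L) {
  stopifnot(nrow(unassigned_reads) > 0, length(candidate_genomes) >= 1,
            inherits(null_genome, "genome"))
  p_un <- count_kmers(unassigned_reads$bases, k = k, label = "unassigned")
  p_null <- genome_profile(null_genome, k = k)
  p_cand <- purrr::map(candidate_genomes, genome_profile, k = k)

  ## abundance-distribution comparisons at a common depth (see
  ## resample_profile): depth differences would otherwise dominate the CvM
  depth <- min(purrr::map_int(c(list(p_un, p_null), p_cand),
                              function(p) as.integer(p$total)))
  x_un <- rel_abundance(resample_profile(p_un, depth, seed = seed))
  cmp_one <- function(p, role) {
    x_ref <- rel_abundance(resample_profile(p, depth, seed = seed + 1L))
    res <- cvm_gof(x_un, x_ref, n_perm = n_perm, seed = seed)
    tibble::tibble(profile = p$label, role = role,
                   cvm_statistic = res$statistic, cvm_p = res$p_value,
                   distance = profile_distance(p_un, p))
  }
  comparisons <- dplyr::bind_rows(
    cmp_one(p_null, "null"),
    purrr::map(p_cand, cmp_one, role = "candidate"))

  cand_rows <- dplyr::filter(comparisons, .data$role == "candidate")
  best <- cand_rows$profile[which.min(cand_rows$distance)]

  clustering <- NULL
  support <- NA_real_
  notice <- NULL
  if (length(p_cand) >= 2) {
    clustering <- hclust_bootstrap(c(list(p_un), p_cand, list(p_null)),
                                   n_boot = n_boot, seed = seed)
    support <- clade_support(clustering, c("unassigned", best))
  } else {
    notice <- "single candidate: clustering skipped, CvM results only"
  }
  structure(list(comparisons = comparisons, best_candidate = best,
                 best_support = support, clustering = clustering,
                 notice = notice),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report>\n")
  print(x$comparisons)
  cat(sprintf("best candidate: %s (pair bootstrap support %s)\n",
              x$best_candidate,
              ifelse(is.na(x$best_support), "n/a",
                     sprintf("%.1f%%", x$best_support))))
  if (!is.null(x$notice)) cat("note:", x$notice, "\n")
  invisible(x)
}

#' Write a k-mer profile as TSV
#'
#' @param profile A [count_kmers()] profile.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(as_tibble.kmer_profile(profile), path)
  invisible(path)
}
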