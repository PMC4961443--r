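#' Aligned-locus container
#'
#' A `locus_alignment` stores one aligned locus as a character matrix over
#' `{A, C, G, T, -, N}` (rows = samples, columns = alignment positions), a
#' logical usable-site mask, and any coded indel characters (appended binary
#' columns, one per distinct gap interval). Column coordinates are 0-based
#' half-open internally; printed reports use 1-based inclusive positions.
#'
#' @param seqs character matrix of single characters; rownames are sample ids.
#' @param locus_name scalar character label.
#' @param usable_mask logical vector, one entry per alignment column.
#'   Defaults to all `TRUE`.
#' @param indels list of `c(start, end)` 1-based inclusive gap intervals
#'   already coded (normally filled in by [code_indels()]).
#' @param indel_states binary matrix (samples x indels).
#' @return an object of class `locus_alignment`.
#' @seealso [read_alignment()], [code_indels()], [collapse_haplotypes()]
#' @export
locus_alignment <- function(seqs, locus_name, usable_mask = NULL,
                            indels = list(), indel_states = NULL) {
  stopifnot(is.matrix(seqs), is.character(seqs))
  if (is.null(rownames(seqs)))
    rownames(seqs) <- paste0("s", seq_len(nrow(seqs)))
  if (anyDuplicated(rownames(seqs)))
    stop("duplicate sample ids in alignment")
  bad <- !(seqs %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) seqs[bad] <- "N"
  if (is.null(usable_mask)) usable_mask <- rep(TRUE, ncol(seqs))
  stopifnot(length(usable_mask) == ncol(seqs))
  if (is.null(indel_states))
    indel_states <- matrix(0L, nrow(seqs), 0L,
                           dimnames = list(rownames(seqs), NULL))
  structure(list(locus_name = locus_name,
                 sample_ids = rownames(seqs),
                 seqs = seqs,
                 usable_mask = as.logical(usable_mask),
                 indels = indels,
                 indel_states = indel_states),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d sequences x %d columns (%d usable + %d indel characters)\n",
              x$locus_name, nrow(x$seqs), ncol(x$seqs),
              sum(x$usable_mask), ncol(x$indel_states)))
  invisible(x)
}

#' Number of usable sites (masked columns plus coded indel characters)
#' @param aln a [locus_alignment()].
#' @export
usable_sites <- function(aln) sum(aln$usable_mask) + ncol(aln$indel_states)

#' Read an aligned FASTA file
#'
#' All records must have the same aligned length. Sequences are uppercased
#' and IUPAC ambiguity codes other than the four bases, `-` and `N` are
#' mapped to `N`. The record id is the description line up to the first
#' whitespace; record order follows file order.
#'
#' @param path FASTA file path.
#' @param locus_name label for the locus; defaults to the file base name.
#' @return a [locus_alignment()].
#' @export
read_alignment <- function(path, locus_name = NULL) {
  locus_name <- locus_name %||% tools::file_path_sans_ext(basename(path))
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(recs), "[ \t]+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment in ", path, ": lengths ",
         paste(unique(lens), collapse = ", "))
  mat <- toupper(do.call(rbind, as.character(recs)))
  dimnames(mat) <- NULL
  rownames(mat) <- ids
  locus_alignment(mat, locus_name)
}

#' Write a locus alignment to FASTA
#' @param aln a [locus_alignment()].
#' @param path output file path.
#' @export
write_alignment <- function(aln, path) {
  lines <- character(2L * nrow(aln$seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$sample_ids)
  lines[c(FALSE, TRUE)] <- apply(aln$seqs, 1L, paste0, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

# maximal single-character runs in a vector; returns list of c(start, end)
.runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts, ends, r$values)
}

#' Mask polymorphic sites inside mononucleotide repeats
#'
#' Mononucleotide microsatellites align ambiguously and mutate fast, so
#' polymorphic positions inside them are excluded from the usable-site mask.
#' A repeat is a single-base run of length `>= min_run` in any sequence
#' (gaps collapsed before run finding). Within such runs, columns that are
#' polymorphic (two or more distinct bases, `N` ignored, or a base/gap
#' contrast) are masked; monomorphic run columns are kept.
#'
#' @param aln a [locus_alignment()].
#' @param min_run minimum run length defining a repeat (default 5; must be
#'   at least 3).
#' @return the filtered [locus_alignment()]. Idempotent.
#' @export
filter_mononucleotide_repeats <- function(aln, min_run = 5L) {
  stopifnot(inherits(aln, "locus_alignment"), min_run >= 3L)
  L <- ncol(aln$seqs)
  candidate <- rep(FALSE, L)
  for (i in seq_len(nrow(aln$seqs))) {
    row <- aln$seqs[i, ]
    keep <- which(row != "-")
    if (length(keep) == 0L) next
    for (run in .runs_of(row[keep])) {
      if (run[[3L]] %in% c("A", "C", "G", "T") &&
          (as.integer(run[[2L]]) - as.integer(run[[1L]]) + 1L) >= min_run) {
        cols <- keep[as.integer(run[[1L]]):as.integer(run[[2L]])]
        candidate[cols] <- TRUE
      }
    }
  }
  poly <- vapply(seq_len(L), function(j) {
    col <- aln$seqs[, j]
    bases <- unique(col[col %in% c("A", "C", "G", "T")])
    length(bases) > 1L || (length(bases) >= 1L && any(col == "-"))
  }, logical(1L))
  aln$usable_mask <- aln$usable_mask & !(candidate & poly)
  aln
}

# maximal gap intervals per row as "start-end" keys
.gap_intervals <- function(row) {
  out <- list()
  for (run in .runs_of(row))
    if (run[[3L]] == "-")
      out[[length(out) + 1L]] <- c(as.integer(run[[1L]]), as.integer(run[[2L]]))
  out
}

#' Code gap intervals as single evolutionary events
#'
#' Each distinct maximal gap interval (identical start and end across the
#' rows sharing it) becomes one appended binary indel character, so a long
#' deletion counts as one step rather than one per base. Alignment columns
#' containing a gap in any row are removed from the usable-site mask; the
#' indel characters are weighted as one step each in distance computations.
#'
#' Recoding an already coded alignment recomputes the same characters, so
#' the operation is idempotent.
#'
#' @param aln a [locus_alignment()].
#' @param min_indel_len only code intervals at least this long (default 1,
#'   i.e. all gap intervals; the conservative superset).
#' @return the recoded [locus_alignment()].
#' @export
code_indels <- function(aln, min_indel_len = 1L) {
  stopifnot(inherits(aln, "locus_alignment"))
  n <- nrow(aln$seqs)
  per_row <- lapply(seq_len(n), function(i) .gap_intervals(aln$seqs[i, ]))
  keys <- unique(unlist(lapply(per_row, function(iv)
    vapply(iv, function(x) paste(x, collapse = "-"), "")), use.names = FALSE))
  if (length(keys)) {
    iv <- do.call(rbind, lapply(strsplit(keys, "-"), as.integer))
    keep <- (iv[, 2L] - iv[, 1L] + 1L) >= min_indel_len
    keys <- keys[keep][order(iv[keep, 1L], iv[keep, 2L])]
  }
  states <- matrix(0L, n, length(keys),
                   dimnames = list(aln$sample_ids, keys))
  for (i in seq_len(n)) {
    rk <- vapply(per_row[[i]], function(x) paste(x, collapse = "-"), "")
    states[i, keys %in% rk] <- 1L
  }
  gapped <- apply(aln$seqs == "-", 2L, any)
  aln$usable_mask <- aln$usable_mask & !gapped
  aln$indels <- lapply(strsplit(keys, "-"), as.integer)
  aln$indel_states <- states
  aln
}

#' Concatenate aligned loci
#'
#' Columns are appended in the given order; rows of later loci are realigned
#' to the sample order of the first locus, so the result does not depend on
#' input row order. Usable-site masks and coded indel characters are carried
#' over (indel coordinates are offset into the concatenated frame).
#'
#' @param alns list of [locus_alignment()] objects with identical sample id
#'   sets.
#' @param locus_name label for the result; defaults to the joined names.
#' @return a [locus_alignment()].
#' @export
concatenate_loci <- function(alns, locus_name = NULL) {
  stopifnot(length(alns) >= 1L)
  if (length(alns) == 1L) return(alns[[1L]])
  ids <- alns[[1L]]$sample_ids
  for (a in alns[-1L])
    if (!setequal(a$sample_ids, ids))
      stop("sample id sets differ between loci ",
           alns[[1L]]$locus_name, " and ", a$locus_name)
  offset <- 0L
  seqs <- NULL; mask <- logical(0); indels <- list(); states <- NULL
  for (a in alns) {
    seqs <- cbind(seqs, a$seqs[ids, , drop = FALSE])
    mask <- c(mask, a$usable_mask)
    indels <- c(indels, lapply(a$indels, function(x) x + offset))
    states <- cbind(states, a$indel_states[ids, , drop = FALSE])
    offset <- offset + ncol(a$seqs)
  }
  locus_name <- locus_name %||%
    paste(vapply(alns, `[[`, "", "locus_name"), collapse = "+")
  locus_alignment(seqs, locus_name, mask, indels,
                  if (is.null(states)) NULL else states)
}

#' Read a population map
#'
#' CSV with header `sample_id,population,lat,lon` (WGS84 decimal degrees).
#'
#' @param path CSV file path.
#' @return data.frame with the four columns, validated.
#' @export
read_popmap <- function(path) {
  pm <- read.csv(path, stringsAsFactors = FALSE)
  validate_popmap(pm)
}

#' @rdname read_popmap
#' @param popmap a data.frame to validate in place.
#' @export
validate_popmap <- function(popmap) {
  need <- c("sample_id", "population", "lat", "lon")
  if (!all(need %in% names(popmap)))
    stop("population map must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(popmap$sample_id))
    stop("duplicate sample ids in population map")
  if (any(abs(popmap$lat) > 90) || any(abs(popmap$lon) > 180))
    stop("latitude/longitude out of range")
  popmap
}

#' Collapse aligned sequences to haplotypes
#'
#' Sequences identical at every usable site and at every coded indel
#' character share a haplotype (exact identity, `N` included as a state).
#' Haplotypes are numbered by first occurrence in the alignment row order.
#'
#' @param aln a [locus_alignment()].
#' @param popmap optional population map (see [read_popmap()]); when given,
#'   per-population haplotype counts are tabulated and every sample must be
#'   mapped.
#' @return an object of class `haplotype_set`: haplotype state matrix
#'   (`hap_seqs`, over usable columns), indel states (`hap_indels`),
#'   per-sample assignment, per-population count table, `k` and `n`.
#' @export
collapse_haplotypes <- function(aln, popmap = NULL) {
  stopifnot(inherits(aln, "locus_alignment"))
  sub <- aln$seqs[, aln$usable_mask, drop = FALSE]
  key <- do.call(paste, c(as.data.frame(cbind(sub, aln$indel_states),
                                        stringsAsFactors = FALSE),
                          sep = ""))
  if (length(key) == 0L) key <- character(nrow(aln$seqs))
  first <- !duplicated(key)
  assignment <- match(key, key[first])
  k <- sum(first)
  hap_seqs <- sub[first, , drop = FALSE]
  hap_indels <- aln$indel_states[first, , drop = FALSE]
  rownames(hap_seqs) <- rownames(hap_indels) <- paste0("H", seq_len(k))
  counts <- NULL
  pops <- NULL
  if (!is.null(popmap)) {
    popmap <- validate_popmap(popmap)
    idx <- match(aln$sample_ids, popmap$sample_id)
    if (anyNA(idx))
      stop("samples missing from population map: ",
           paste(aln$sample_ids[is.na(idx)], collapse = ", "))
    pops <- popmap$population[idx]
    counts <- table(haplotype = factor(paste0("H", assignment),
                                       levels = paste0("H", seq_len(k))),
                    population = pops)
  }
  structure(list(hap_seqs = hap_seqs, hap_indels = hap_indels,
                 assignment = assignment, sample_ids = aln$sample_ids,
                 populations = pops, counts = counts,
                 k = k, n = nrow(aln$seqs), L = usable_sites(aln),
                 locus_name = aln$locus_name),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %s: k = %d haplotypes among n = %d samples (%d usable sites)\n",
              x$locus_name, x$k, x$n, x$L))
  invisible(x)
}

#' Haplotype counts (pooled or per population)
#' @param hapset a [collapse_haplotypes()] result.
#' @return integer vector of pooled haplotype counts.
#' @export
haplotype_counts <- function(hapset) {
  tabulate(hapset$assignment, nbins = hapset$k)
}

#' Write the haplotype table as TSV
#'
#' One row per haplotype with its collapsed sequence and, if populations are
#' known, per-population counts.
#' @param hapset a [collapse_haplotypes()] result.
#' @param path output path.
#' @export
write_haplotype_table <- function(hapset, path) {
  df <- data.frame(haplotype = rownames(hapset$hap_seqs),
                   sequence = apply(cbind(hapset$hap_seqs, hapset$hap_indels),
                                    1L, paste0, collapse = ""),
                   total = haplotype_counts(hapset),
                   stringsAsFactors = FALSE)
  if (!is.null(hapset$counts))
    df <- cbind(df, as.data.frame.matrix(unclass(hapset$counts)))
  write_tsv(df, path)
}

# pairwise distances between haplotypes: number of differing usable sites
# (pairwise deletion of N) plus one step per differing indel character;
# also returns the number of compared sites for each pair
hap_distances <- function(hapset) {
  k <- hapset$k
  d <- matrix(0, k, k)
  l <- matrix(0, k, k)
  s <- hapset$hap_seqs
  ind <- hapset$hap_indels
  for (i in seq_len(max(k - 1L, 0L))) {
    for (j in (i + 1L):k) {
      ok <- s[i, ] != "N" & s[j, ] != "N"
      dij <- sum(s[i, ok] != s[j, ok])
      if (ncol(ind) > 0L) dij <- dij + sum(ind[i, ] != ind[j, ])
      d[i, j] <- d[j, i] <- dij
      l[i, j] <- l[j, i] <- sum(ok) + ncol(ind)
    }
  }
  diag(l) <- ncol(s) + ncol(ind)
  list(d = d, sites = l)
}
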