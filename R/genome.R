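#' Genome objects
#'
#' A `genome` is a lightweight record holding a single DNA sequence over
#' the strict alphabet `{A, C, G, T}` together with an identifier and an
#' optional free-text description. Simulated genomes never contain `N`.
#'
#' @param id Single string, the sequence identifier.
#' @param sequence Single string over `A`, `C`, `G`, `T`.
#' @param description Optional free-text description.
#'
#' @return An object of class `genome` with elements `id`, `sequence`
#'   and `description`.
#' @export
#' @examples
#' g <- genome("toy", "ACGTACGT")
#' gc_content(g)
genome <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) {
    stop("genome sequence must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("genome sequence restricted to alphabet {A,C,G,T}", call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, description = description),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp, GC %.3f\n",
              x$id, format(nchar(x$sequence), big.mark = ","), gc_content(x)))
  invisible(x)
}

#' @export
length.genome <- function(x) nchar(x$sequence)

#' Realized GC fraction of a genome
#'
#' @param g A [genome()].
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(g) {
  stopifnot(inherits(g, "genome"))
  counts <- base_counts(g$sequence)
  unname((counts[["G"]] + counts[["C"]]) / sum(counts))
}

base_counts <- function(sequence) {
  f <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                   letters = c("A", "C", "G", "T"))
  stats::setNames(as.numeric(f), c("A", "C", "G", "T"))
}

#' Generate a random genome of given GC content
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`, the simplest composition model matching a
#' target GC fraction.
#'
#' @param length Genome length in bp (`>= 1`).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Integer seed; the same `(length, gc, seed)` always yields the
#'   identical sequence.
#' @param id Sequence identifier.
#'
#' @return A [genome()].
#' @export
#' @examples
#' g <- generate_genome(1000, gc = 0.5, seed = 1)
generate_genome <- function(length, gc, seed, id = "sim_genome") {
  if (length < 1) stop("genome length must be >= 1", call. = FALSE)
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]", call. = FALSE)
  bases <- withr::with_seed(seed, {
    sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  genome(id, paste(bases, collapse = ""),
         description = sprintf("simulated, target GC %.3f", gc))
}

#' Generate an artificial null genome of uniform base composition
#'
#' All four bases are drawn i.i.d. with probability 1/4, so the purine
#' fraction concentrates at 0.5 and every k-mer is equally likely. This is
#' the compositional null against which read-set k-mer profiles are
#' compared. Base frequencies other than uniform can be obtained with
#' [generate_genome()].
#'
#' @param length Genome length in bp (`>= 1`).
#' @param seed Integer seed.
#' @param id Sequence identifier.
#'
#' @return A [genome()].
#' @export
generate_null_genome <- function(length, seed, id = "null_genome") {
  if (length < 1) stop("genome length must be >= 1", call. = FALSE)
  bases <- withr::with_seed(seed, {
    sample(c("A", "C", "G", "T"), size = length, replace = TRUE)
  })
  genome(id, paste(bases, collapse = ""),
         description = "artificial null genome, uniform base composition")
}

#' Read and write genomes as FASTA
#'
#' @param g A [genome()] or list of genomes (for writing).
#' @param path File path.
#' @return `read_genome_fasta()` returns a list of [genome()] objects,
#'   one per FASTA record; `write_genome_fasta()` returns `path`
#'   invisibly.
#' @export
write_genome_fasta <- function(g, path) {
  if (inherits(g, "genome")) g <- list(g)
  seqs <- Biostrings::DNAStringSet(vapply(g, `[[`, "", "sequence"))
  names(seqs) <- vapply(g, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  purrr::map2(names(seqs), as.character(seqs), function(nm, s) {
    genome(sub("\\s.*$", "", nm), s, description = nm)
  })
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
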