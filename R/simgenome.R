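# Synthetic genomes with planted Merlin-like TIR elements and full ground
# truth. Every downstream detector (ORF/motif scan, translated search,
# boundary/TIR/TSD inference, family assignment, tandem repeats,
# contamination screen) is exercised against genomes built here.

#' Specify a planted transposon family
#'
#' A `FamilySpec` describes one family of planted elements: TIR length and
#' imperfection, TSD length, transposase ORF size, copy number, per-copy
#' divergence and pseudogenization, and an optional internal tandem-repeat
#' tract.
#'
#' @param family_id label, e.g. `"F1"`
#' @param tir_length TIR length in bp, within `[10, 462]`
#' @param tsd_length target site duplication length, one of 7:10 (Merlin uses 8-9)
#' @param orf_length transposase protein length in residues
#' @param n_copies number of planted copies
#' @param per_copy_divergence substitution probability per site applied to each
#'   copy (0 to 0.5)
#' @param tir_mismatches Hamming mismatches planted between the 5' TIR and the
#'   reverse complement of the 3' TIR (must be `< tir_length`)
#' @param frameshift_fraction fraction of copies receiving an ORF indel
#' @param remnant_fraction fraction of copies truncated to a 40-80% fragment
#' @param n_segdup extra copies created by duplicating copy 1 together with its
#'   flanks (segmental duplication, not transposition)
#' @param tandem_spec optional list(period=, units=, nested=list(period=, units=))
#'   describing a tandem-repeat tract planted in the 5' internal region
#' @param terminal_gg should the 5' TIR start with GG (and the 3' end with CC)?
#' @param element_length optional total element length in bp; internal spacer
#'   lengths are solved to match
#' @param spacing12,spacing23 residue spacing ranges between the DDE blocks of
#'   the planted transposase
#' @return a `FamilySpec` list
#' @export
family_spec <- function(family_id, tir_length = 30L, tsd_length = 8L,
                        orf_length = 300L, n_copies = 3L,
                        per_copy_divergence = 0, tir_mismatches = 0L,
                        frameshift_fraction = 0, remnant_fraction = 0,
                        n_segdup = 0L, tandem_spec = NULL, terminal_gg = TRUE,
                        element_length = NULL,
                        spacing12 = c(50L, 70L), spacing23 = c(15L, 35L)) {
  spec <- list(family_id = family_id, tir_length = as.integer(tir_length),
               tsd_length = as.integer(tsd_length), orf_length = as.integer(orf_length),
               n_copies = as.integer(n_copies),
               per_copy_divergence = per_copy_divergence,
               tir_mismatches = as.integer(tir_mismatches),
               frameshift_fraction = frameshift_fraction,
               remnant_fraction = remnant_fraction, n_segdup = as.integer(n_segdup),
               tandem_spec = tandem_spec, terminal_gg = isTRUE(terminal_gg),
               element_length = element_length,
               spacing12 = as.integer(spacing12), spacing23 = as.integer(spacing23))
  validate_family_spec(spec)
  structure(spec, class = "FamilySpec")
}

validate_family_spec <- function(spec) {
  if (spec$tir_length < 10L || spec$tir_length > 462L)
    stop("FamilySpec field 'tir_length' must be in [10, 462], got ", spec$tir_length)
  if (!spec$tsd_length %in% 7:10)
    stop("FamilySpec field 'tsd_length' must be one of 7,8,9,10, got ", spec$tsd_length)
  if (spec$per_copy_divergence < 0 || spec$per_copy_divergence > 0.5)
    stop("FamilySpec field 'per_copy_divergence' must be in [0, 0.5]")
  if (spec$tir_mismatches >= spec$tir_length)
    stop("FamilySpec field 'tir_mismatches' must be < tir_length")
  if (spec$n_copies < 1L) stop("FamilySpec field 'n_copies' must be >= 1")
  invisible(spec)
}

# random protein built around the three DDE consensus blocks
sim_transposase <- function(orf_length, profile = dde_profile(),
                            spacing12 = c(50L, 70L), spacing23 = c(15L, 35L)) {
  cons <- profile$consensus
  gap12 <- sample(spacing12[1]:spacing12[2], 1)
  gap23 <- sample(spacing23[1]:spacing23[2], 1)
  core <- paste0(cons[1], rand_aa(gap12), cons[2], rand_aa(gap23), cons[3])
  ncore <- nchar(core)
  extra <- orf_length - 1L - ncore              # minus leading M
  if (extra < 0) stop("orf_length too short for the domain core (needs >= ",
                      ncore + 1L, " aa)")
  nterm <- min(extra, max(10L, round(extra * 0.4)))
  cterm <- extra - nterm
  paste0("M", rand_aa(nterm), core, rand_aa(cterm))
}

rand_aa <- function(n) if (n <= 0) "" else
  paste(sample(setdiff(AA20, "M"), n, replace = TRUE), collapse = "")

SYN_CODONS <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)

# reverse-translate a protein, sampling synonymous codons; appends TAA stop
reverse_translate <- function(protein) {
  aa <- chars(protein)
  codons <- vapply(aa, function(a) {
    cs <- SYN_CODONS[[a]]
    if (is.null(cs)) stop("cannot reverse-translate residue ", a)
    if (length(cs) == 1L) cs else sample(cs, 1)
  }, "")
  paste0(paste(codons, collapse = ""), "TAA")
}

# tandem tract: units x period, optionally with a nested repeat inside the unit
sim_tandem_tract <- function(tandem_spec) {
  p <- tandem_spec$period
  if (!is.null(tandem_spec$nested)) {
    np <- tandem_spec$nested$period; nu <- tandem_spec$nested$units
    inner <- strrep(random_dna(np), nu)
    rest <- p - nchar(inner)
    if (rest < 0) stop("nested repeat does not fit in the unit")
    pre <- random_dna(ceiling(rest / 2)); post <- random_dna(floor(rest / 2))
    unit <- paste0(pre, inner, post)
  } else unit <- random_dna(p)
  units <- tandem_spec$units
  full <- floor(units)
  frac <- round((units - full) * p)
  paste0(strrep(unit, full), substr(unit, 1, frac))
}

# sample mismatch positions spread as in real imperfect TIRs: no runs of 3+
# consecutive mismatches, and no prefix of length >= 8 that is mismatched at
# more than half of its positions
sample_mismatch_pos <- function(len, k, protect = integer(0)) {
  if (k == 0) return(integer(0))
  for (try in 1:2000) {
    pos <- sort(sample(setdiff(seq_len(len), protect), k))
    runs <- rle(diff(pos) == 1L)
    if (any(runs$values & runs$lengths >= 2L)) next       # 3 consecutive
    cum <- cumsum(tabulate(pos, nbins = len))
    if (any(cum[8:len] / (8:len) > 0.5)) next
    return(pos)
  }
  stop("cannot place ", k, " TIR mismatches in ", len, " bp without clumps")
}

mutate_bases <- function(seq, pos) {
  v <- chars(seq)
  v[pos] <- vapply(v[pos], function(b) sample(setdiff(DNA_BASES, b), 1), "")
  paste(v, collapse = "")
}

# build one master element for a family; returns element pieces and metadata
build_master_element <- function(spec, profile = dde_profile()) {
  tir5 <- paste0(if (spec$terminal_gg) "GG" else random_dna(2),
                 random_dna(spec$tir_length - 2L))
  # protect the outer GG and the two innermost positions: the TIR ends define
  # its length, so they must not be planted as mismatches
  protect <- c(if (spec$terminal_gg) 1:2 else integer(0),
               spec$tir_length - 1L, spec$tir_length)
  mm <- sample_mismatch_pos(spec$tir_length, spec$tir_mismatches, protect)
  tir3 <- revcomp(mutate_bases(tir5, mm))
  protein <- sim_transposase(spec$orf_length, profile, spec$spacing12, spec$spacing23)
  orf_nt <- reverse_translate(protein)
  tract <- if (!is.null(spec$tandem_spec)) sim_tandem_tract(spec$tandem_spec) else ""
  fixed <- 2L * spec$tir_length + nchar(orf_nt) + nchar(tract) + 3L  # +TAA guard
  if (!is.null(spec$element_length)) {
    slack <- spec$element_length - fixed
    if (slack < 20L) stop("element_length too small for spec ", spec$family_id)
    u5 <- ceiling(slack * 0.6); u3 <- slack - u5
  } else { u5 <- 60L; u3 <- 40L }
  utr5 <- paste0(random_dna(u5), tract)
  # in-frame stop just upstream of the ATG so the planted ORF is maximal
  utr5 <- paste0(utr5, "TAA")
  utr3 <- random_dna(u3)
  # make the TIR non-extendable inward: force the first three inner base
  # pairs to mismatch (utr5 start vs complement of utr3 end), so the planted
  # length is the unambiguous optimum for any extension rule
  u5v <- chars(utr5); u3v <- chars(utr3); n3 <- length(u3v)
  for (i in 1:3) {
    if (u5v[i] == COMPLEMENT[u3v[n3 - i + 1L]])
      u3v[n3 - i + 1L] <- sample(setdiff(DNA_BASES, COMPLEMENT[u5v[i]]), 1)
  }
  utr3 <- paste(u3v, collapse = "")
  element <- paste0(tir5, utr5, orf_nt, utr3, tir3)
  list(element = element, tir5 = tir5, tir3 = tir3, protein = protein,
       orf_start = spec$tir_length + nchar(utr5),          # 0-based in element
       orf_end = spec$tir_length + nchar(utr5) + nchar(orf_nt),
       tract_start = if (nzchar(tract)) spec$tir_length + u5 else NA_integer_,
       tract_len = nchar(tract))
}

#' Apply substitutions and indels to a DNA sequence
#'
#' Substitutions are i.i.d. Bernoulli per site at `sub_rate` (or, with
#' `exact = TRUE`, exactly `round(sub_rate * nchar(seq))` distinct sites),
#' each replaced by a different base. Indels are planted at `indel_rate`
#' per site, each a 1-2 bp insertion or deletion.
#'
#' @param seq DNA string
#' @param sub_rate substitution probability per site, in `[0, 1)`
#' @param indel_rate indel probability per site, in `[0, 1)`
#' @param seed optional integer; when given the mutation is reproducible
#' @param exact plant exactly `round(sub_rate * length)` substitutions
#' @return mutated DNA string
#' @export
mutate_copy <- function(seq, sub_rate, indel_rate = 0, seed = NULL, exact = FALSE) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  seq <- check_dna(seq, "mutate_copy input")
  run <- function() {
    n <- nchar(seq)
    v <- chars(seq)
    pos <- if (exact) sample(n, round(sub_rate * n))
           else which(runif(n) < sub_rate)
    for (p in pos) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1)
    out <- paste(v, collapse = "")
    n_ind <- rbinom(1, n, indel_rate)
    for (i in seq_len(n_ind)) {
      at <- sample(nchar(out) - 3L, 1)
      w <- sample(1:2, 1)
      if (runif(1) < 0.5) out <- paste0(substr(out, 1, at), substr(out, at + w + 1L, nchar(out)))
      else out <- paste0(substr(out, 1, at), random_dna(w), substr(out, at + 1L, nchar(out)))
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# revert substitutions that break the reading frame structure: premature
# stops, a lost ATG start, or a lost terminal stop
revert_orf_stops <- function(mutated, original, orf_start, orf_end) {
  v <- chars(mutated); o <- chars(original)
  gc <- Biostrings::GENETIC_CODE
  last_cod <- orf_end - 3L
  for (p in seq(orf_start + 3L, last_cod - 3L, by = 3L)) {
    cod <- paste0(v[p + 1L], v[p + 2L], v[p + 3L])
    if (!is.na(gc[cod]) && gc[cod] == "*")
      v[p + 1:3] <- o[p + 1:3]
  }
  v[orf_start + 1:3] <- o[orf_start + 1:3]      # ATG
  v[last_cod + 1:3] <- o[last_cod + 1:3]        # terminal stop
  paste(v, collapse = "")
}

random_tsd <- function(k, avoid = character(0)) {
  repeat {
    t <- random_dna(k)
    v <- chars(t)
    if (length(unique(v)) == 1L) next                 # homopolymer extends
    if (v[k] == COMPLEMENT[v[1]]) next                # would extend TIR outward
    if (!t %in% avoid) return(t)
  }
}

#' Simulate a genome with planted elements and ground truth
#'
#' Plants every copy requested by `specs` into an i.i.d. random background,
#' flanked by per-copy TSDs drawn independently (so TSDs differ among copies,
#' the signature of true transposition). Optionally adds bacterial-like
#' contaminant contigs whose ORFs are copied (with ~2% mutation) from a decoy
#' protein set.
#'
#' @param specs list of [family_spec()] objects (a single spec is accepted)
#' @param background_length host contig length in bp before insertion
#' @param contaminant_count number of contaminant contigs to add
#' @param seed integer seed; fixed seed fixes all outputs byte-for-byte
#' @param gc background GC content
#' @param decoys optional character vector of decoy proteins (default
#'   [decoy_proteins()] regenerated under `seed`)
#' @param minus_fraction fraction of copies planted on the minus strand
#' @return list with `genome` (named character vector of contigs) and `truth`
#'   (a `SimTruth`: `$copies` data.frame with 0-based half-open coordinates,
#'   `$contaminants`, `$proteins`, `$seed`)
#' @export
simulate_genome <- function(specs, background_length = 50000L,
                            contaminant_count = 0L, seed = 1L, gc = 0.5,
                            decoys = NULL, minus_fraction = 0,
                            min_gap = 400L) {
  if (inherits(specs, "FamilySpec")) specs <- list(specs)
  lapply(specs, validate_family_spec)
  with_seed(seed, {
    profile <- dde_profile()
    masters <- lapply(specs, build_master_element, profile = profile)
    footprint <- sum(vapply(seq_along(specs), function(i)
      (nchar(masters[[i]]$element) + 2L * specs[[i]]$tsd_length + 200L) *
        (specs[[i]]$n_copies + specs[[i]]$n_segdup), 0))
    if (background_length < footprint)
      stop("background_length (", background_length,
           ") smaller than total element footprint (", footprint, ")")

    inserts <- list()   # each: list(seq, meta-row)
    used_tsds <- character(0)
    for (fi in seq_along(specs)) {
      spec <- specs[[fi]]; m <- masters[[fi]]
      n_fs <- round(spec$frameshift_fraction * spec$n_copies)
      n_rm <- round(spec$remnant_fraction * spec$n_copies)
      status <- c(rep("frameshifted", n_fs), rep("remnant", n_rm),
                  rep("intact", max(0L, spec$n_copies - n_fs - n_rm)))
      status <- status[seq_len(spec$n_copies)]
      for (ci in seq_len(spec$n_copies)) {
        el <- m$element
        nsub <- NA_integer_
        if (spec$per_copy_divergence > 0) {
          el2 <- mutate_copy(el, spec$per_copy_divergence)
          # purifying selection: intact copies keep a readable transposase,
          # so substitutions that create premature stops are reverted
          el2 <- revert_orf_stops(el2, m$element, m$orf_start, m$orf_end)
          nsub <- hamming(el, el2); el <- el2
        } else nsub <- 0L
        if (status[ci] == "frameshifted") {
          # 1-bp deletion inside the ORF
          at <- m$orf_start + sample(50:(m$orf_end - m$orf_start - 60L), 1)
          el <- paste0(substr(el, 1, at), substr(el, at + 2L, nchar(el)))
        }
        if (status[ci] == "remnant") {
          keep <- runif(1, 0.4, 0.8)
          side <- sample(c("5", "3"), 1)
          w <- round(keep * nchar(el))
          el <- if (side == "5") substr(el, 1, w) else substr(el, nchar(el) - w + 1L, nchar(el))
        }
        tsd <- if (status[ci] == "remnant") "" else random_tsd(spec$tsd_length, used_tsds)
        if (nzchar(tsd)) used_tsds <- c(used_tsds, tsd)
        strand <- if (runif(1) < minus_fraction) "-" else "+"
        if (strand == "-") el <- revcomp(el)
        inserts[[length(inserts) + 1L]] <- list(
          seq = paste0(tsd, el, tsd), tsd = tsd, elen = nchar(el),
          family_id = spec$family_id, status = status[ci], strand = strand,
          tir_length = spec$tir_length, tir_mismatches = spec$tir_mismatches,
          n_subs = nsub, copy_in_family = ci)
      }
      for (si in seq_len(spec$n_segdup)) {
        # duplicate the first copy together with 300 bp of synthetic shared flank
        first <- inserts[[which(vapply(inserts, function(x)
          x$family_id == spec$family_id && x$copy_in_family == 1L, NA))[1]]]
        shared5 <- random_dna(300); shared3 <- random_dna(300)
        # plant the SAME shared flanks around both: rebuild first with them
        inserts[[length(inserts) + 1L]] <- list(
          seq = paste0(shared5, first$seq, shared3), tsd = first$tsd,
          elen = first$elen, family_id = spec$family_id, status = "segdup",
          strand = first$strand, tir_length = spec$tir_length,
          tir_mismatches = spec$tir_mismatches, n_subs = first$n_subs,
          copy_in_family = spec$n_copies + si, shared_flank = 300L,
          partner = 1L)
        # tag the partner copy too: wrap it with the same shared flanks
        idx <- which(vapply(inserts, function(x)
          x$family_id == spec$family_id && x$copy_in_family == 1L, NA))[1]
        if (is.null(inserts[[idx]]$shared_flank)) {
          inserts[[idx]]$seq <- paste0(shared5, inserts[[idx]]$seq, shared3)
          inserts[[idx]]$shared_flank <- 300L
        }
      }
    }
    # shuffle insertion order, then place sequentially with random gaps
    inserts <- inserts[sample(seq_along(inserts))]
    total_ins <- sum(vapply(inserts, function(x) nchar(x$seq), 0))
    gap_budget <- background_length - 0  # background bases form the gaps
    ngap <- length(inserts) + 1L
    cuts <- sort(sample(seq_len(gap_budget - 1L), ngap - 1L))
    gaps <- diff(c(0L, cuts, gap_budget))
    gaps <- round(pmax(gaps, min_gap) * gap_budget / sum(pmax(gaps, min_gap)))
    gaps <- pmax(gaps, min_gap)
    bg <- random_dna(sum(gaps), gc)
    pieces <- character(0); rows <- list(); pos <- 0L; bgpos <- 0L
    for (i in seq_along(inserts)) {
      g <- gaps[i]
      pieces <- c(pieces, substr(bg, bgpos + 1L, bgpos + g)); bgpos <- bgpos + g
      pos <- pos + g
      ins <- inserts[[i]]
      shared <- ins$shared_flank %||% 0L
      el_start <- pos + shared + nchar(ins$tsd)
      rows[[i]] <- data.frame(
        copy_id = NA_character_, contig = "contig_1",
        start = el_start, end = el_start + ins$elen, strand = ins$strand,
        family_id = ins$family_id, copy_in_family = ins$copy_in_family,
        tsd = ins$tsd, tsd_len = nchar(ins$tsd),
        tir_length = ins$tir_length, tir_mismatches = ins$tir_mismatches,
        status = ins$status, n_subs = ins$n_subs,
        shared_flank = shared, stringsAsFactors = FALSE)
      pieces <- c(pieces, ins$seq)
      pos <- pos + nchar(ins$seq)
    }
    pieces <- c(pieces, substr(bg, bgpos + 1L, nchar(bg)))
    contig <- paste(pieces, collapse = "")
    genome <- c(contig_1 = contig)

    copies <- if (length(rows)) do.call(rbind, rows) else empty_truth_copies()
    if (nrow(copies)) {
      ord <- order(copies$start)
      copies <- copies[ord, , drop = FALSE]
      copies$copy_id <- sprintf("%s_c%02d", copies$family_id, copies$copy_in_family)
      rownames(copies) <- NULL
    }

    if (is.null(decoys)) decoys <- decoy_proteins(8L)
    contaminants <- character(0)
    if (contaminant_count > 0) {
      for (ci in seq_len(contaminant_count)) {
        nm <- sprintf("contam_%d", ci)
        orfs <- vapply(sample(decoys, 3L), function(p) {
          nt <- reverse_translate(chars_to_protein(p))
          mutate_copy(nt, 0.02)
        }, "")
        seqs <- c(random_dna(400, gc), orfs[1], random_dna(300, gc), orfs[2],
                  random_dna(300, gc), orfs[3], random_dna(400, gc))
        genome[nm] <- paste(seqs, collapse = "")
        contaminants <- c(contaminants, nm)
      }
    }
    truth <- structure(list(copies = copies, contaminants = contaminants,
                            seed = as.integer(seed), decoys = decoys,
                            proteins = setNames(vapply(masters, `[[`, "", "protein"),
                                                vapply(specs, `[[`, "", "family_id")),
                            masters = setNames(vapply(masters, `[[`, "", "element"),
                                               vapply(specs, `[[`, "", "family_id"))),
                       class = "SimTruth")
    list(genome = genome, truth = truth)
  })
}

chars_to_protein <- function(p) p  # decoys are plain strings already

empty_truth_copies <- function() data.frame(
  copy_id = character(), contig = character(), start = integer(), end = integer(),
  strand = character(), family_id = character(), copy_in_family = integer(),
  tsd = character(), tsd_len = integer(), tir_length = integer(),
  tir_mismatches = integer(), status = character(), n_subs = integer(),
  shared_flank = integer(), stringsAsFactors = FALSE)

#' Generate a synthetic bacterial-like decoy protein set
#'
#' Random proteins used as the contamination reference in tests and
#' simulations; real analyses should supply a genuine bacterial protein FASTA.
#'
#' @param n number of proteins
#' @param len_range length range in residues
#' @param seed optional seed
#' @return named character vector of proteins
#' @export
decoy_proteins <- function(n = 8L, len_range = c(220L, 320L), seed = NULL) {
  run <- function() {
    setNames(vapply(seq_len(n), function(i)
      paste0("M", rand_aa(sample(len_range[1]:len_range[2], 1))), ""),
      sprintf("decoy_%02d", seq_len(n)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ---- truth serialisation ---------------------------------------------------

#' Write / read simulation ground truth
#'
#' `write_truth` writes a TSV of planted copies plus a GFF3 with element
#' features and TIR/TSD child features; `read_truth` round-trips the TSV.
#'
#' @param truth a `SimTruth`
#' @param prefix output path prefix; writes `<prefix>.tsv` and `<prefix>.gff3`
#' @return `write_truth` returns the two paths invisibly; `read_truth` a `SimTruth`
#' @export
write_truth <- function(truth, prefix) {
  tsv <- paste0(prefix, ".tsv"); gff <- paste0(prefix, ".gff3")
  df <- truth$copies
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("# contaminants: %s",
                       paste(truth$contaminants, collapse = ",")),
               sprintf("# seed: %d", truth$seed)),
             con = paste0(prefix, ".meta"))
  gr <- truth_granges(truth)
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(tsv = tsv, gff = gff))
}

truth_granges <- function(truth) {
  df <- truth$copies
  if (!nrow(df)) {
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges()))
  }
  el <- GenomicRanges::GRanges(df$contig,
          IRanges::IRanges(df$start + 1L, df$end), strand = df$strand,
          type = "transposable_element", ID = df$copy_id,
          family_id = df$family_id, status = df$status, tsd = df$tsd)
  kids <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (r$status %in% c("intact", "frameshifted", "segdup")) {
      kids[[length(kids) + 1L]] <- GenomicRanges::GRanges(r$contig,
        IRanges::IRanges(c(r$start + 1L, r$end - r$tir_length + 1L),
                         c(r$start + r$tir_length, r$end)),
        strand = r$strand, type = "terminal_inverted_repeat",
        ID = paste0(r$copy_id, c("_tir5", "_tir3")), Parent = r$copy_id)
      if (r$tsd_len > 0)
        kids[[length(kids) + 1L]] <- GenomicRanges::GRanges(r$contig,
          IRanges::IRanges(c(r$start - r$tsd_len + 1L, r$end + 1L),
                           c(r$start, r$end + r$tsd_len)),
          strand = "*", type = "target_site_duplication",
          ID = paste0(r$copy_id, c("_tsd5", "_tsd3")), Parent = r$copy_id)
    }
  }
  if (length(kids)) suppressWarnings(c(el, do.call(c, kids))) else el
}

#' @rdname write_truth
#' @export
read_truth <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  df <- read.table(tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(tsd = "character"))
  df$tsd[is.na(df$tsd)] <- ""
  meta <- readLines(paste0(prefix, ".meta"))
  cont <- sub("^# contaminants: ?", "", meta[1])
  cont <- if (nzchar(cont)) strsplit(cont, ",")[[1]] else character(0)
  seed <- as.integer(sub("^# seed: ", "", meta[2]))
  structure(list(copies = df, contaminants = cont, seed = seed),
            class = "SimTruth")
}

# ---- targeted constructions for diverged-copy emulation --------------------

#' Construct a pair of diverged coding copies with controlled identities
#'
#' Emulates a pair of anciently diverged transposase copies under purifying
#' selection: a target count of nonsynonymous differences is planted in the
#' conserved core (first/second codon positions) and the remaining
#' substitutions are synonymous third-position changes at fourfold-degenerate
#' codons. This yields a pair with a prescribed nucleotide divergence over
#' the ORF and a prescribed amino-acid divergence over the core.
#'
#' @param aa_len protein length in residues (ORF nt length is `3*(aa_len+1)`)
#' @param core_len length of the conserved core (centred) in residues
#' @param nt_divergence target proportion of differing nucleotide sites
#' @param core_aa_divergence target proportion of differing residues in the core
#' @param seed integer seed
#' @return list with `nt1`, `nt2` (ORF DNA incl. stop), `aa1`, `aa2`,
#'   `core` (1-based residue range of the core)
#' @export
sim_diverged_orf_pair <- function(aa_len = 253L, core_len = 199L,
                                  nt_divergence = 0.15,
                                  core_aa_divergence = 0.19, seed = 1L) {
  with_seed(seed, {
    prot <- paste0("M", rand_aa(aa_len - 1L))
    nt1 <- reverse_translate(prot)
    L <- nchar(nt1)
    core_start <- ((aa_len - core_len) %/% 2) + 1L
    core <- core_start:(core_start + core_len - 1L)
    n_aa_diff <- round(core_aa_divergence * core_len)
    n_nt <- round(nt_divergence * L)
    v <- chars(nt1)
    # nonsynonymous: mutate the 2nd codon position (always nonsynonymous)
    aa_sites <- sample(setdiff(core, 1L), n_aa_diff)
    for (a in aa_sites) {
      p <- (a - 1L) * 3L + 2L
      v[p] <- sample(setdiff(DNA_BASES, v[p]), 1)
    }
    # synonymous: third-position changes that preserve the encoded residue
    gc <- Biostrings::GENETIC_CODE
    remaining <- n_nt - n_aa_diff
    syn_alt <- lapply(seq_len(aa_len), function(a) {
      p <- (a - 1L) * 3L
      cod <- paste0(v[p + 1L], v[p + 2L], v[p + 3L])
      alts <- paste0(v[p + 1L], v[p + 2L], setdiff(DNA_BASES, v[p + 3L]))
      alts[gc[alts] == gc[cod]]
    })
    cand <- setdiff(which(lengths(syn_alt) > 0L), c(aa_sites, 1L))
    if (length(cand) < remaining)
      stop("not enough synonymous sites for the requested divergence")
    for (a in sample(cand, remaining)) {
      p <- a * 3L
      v[p] <- substr(sample(syn_alt[[a]], 1), 3L, 3L)
    }
    nt2 <- paste(v, collapse = "")
    aa2 <- translate_str(nt2)
    aa2 <- sub("\\*$", "", aa2)
    list(nt1 = nt1, nt2 = nt2, aa1 = prot, aa2 = aa2, core = range(core))
  })
}

#' Construct a homologous protein pair at a prescribed identity
#'
#' Builds protein B from protein A's conserved region: a set fraction of
#' positions kept identical, a further fraction replaced by similar residues
#' (positive BLOSUM62 pairs), the rest by dissimilar residues; regions outside
#' the shared core are unrelated. Used to emulate distant cross-species
#' transposase comparisons.
#'
#' @param region_len length of the homologous region (residues)
#' @param identity fraction of identical positions in the region
#' @param similarity fraction of identical-or-similar positions (>= identity)
#' @param tail_len unrelated residues appended to each side of protein B
#' @param seed integer seed
#' @return list with `a`, `b` proteins and `region` (range in `a`)
#' @export
sim_homolog_pair <- function(region_len = 219L, identity = 0.43,
                             similarity = 0.64, tail_len = c(30L, 180L),
                             seed = 1L) {
  sim_pairs <- list(A = "S", R = "K", N = "D", D = "E", Q = "E", E = "D",
                    H = "Y", I = "V", L = "M", K = "R", M = "L", F = "Y",
                    S = "T", T = "S", W = "Y", Y = "F", V = "I")
  with_seed(seed, {
    reg_a <- chars(paste0(rand_aa(region_len)))
    n_id <- round(identity * region_len)
    n_sim <- round((similarity - identity) * region_len)
    # keep the region ends identical so local alignment spans it fully
    anchor <- c(1:6, (region_len - 5L):region_len)
    ids <- c(anchor, sample(setdiff(seq_len(region_len), anchor), n_id - length(anchor)))
    rest <- setdiff(seq_len(region_len), ids)
    sims <- sample(rest, n_sim)
    diffs <- setdiff(rest, sims)
    reg_b <- reg_a
    for (p in sims) {
      s <- sim_pairs[[reg_a[p]]]
      reg_b[p] <- if (!is.null(s)) s else "G"
    }
    for (p in diffs) {
      cand <- setdiff(AA20, c(reg_a[p], sim_pairs[[reg_a[p]]] %||% character(0)))
      reg_b[p] <- sample(cand, 1)
    }
    a <- paste0("M", rand_aa(20L), paste(reg_a, collapse = ""), rand_aa(12L))
    b <- paste0("M", rand_aa(tail_len[1]), paste(reg_b, collapse = ""), rand_aa(tail_len[2]))
    list(a = a, b = b, region = c(22L, 22L + region_len - 1L))
  })
}
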