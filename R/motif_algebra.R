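#' @importFrom Biostrings DNAString DNAStringSet matchPattern reverseComplement
#'   IUPAC_CODE_MAP writeXStringSet readDNAStringSet
#' @importFrom stats rnorm rpois rchisq rgamma runif pt setNames
#' @importFrom utils read.delim write.table
NULL

IUPAC_ALPHABET <- names(Biostrings::IUPAC_CODE_MAP)

MOD_TYPES <- c("m6A", "m4C", "m5C", "unknown")

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code Single IUPAC character (one of A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @return Character vector of the bases the code stands for, e.g. `W` ->
#'   `c("A","T")`, `N` -> `c("A","C","G","T")`.
#' @export
iupac_expand <- function(code) {
  if (!is.character(code) || length(code) != 1L || !code %in% IUPAC_ALPHABET) {
    stop("invalid IUPAC code: ", deparse(code))
  }
  strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
}

# vectorised base-set lookup for a pattern string -> list of base vectors
pattern_base_sets <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, IUPAC_ALPHABET)
  if (length(bad)) stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "))
  lapply(chars, function(ch) strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]])
}

#' Construct a degenerate methylated motif
#'
#' A motif is an IUPAC pattern with one designated methylated base. The base
#' set at the methylated offset must be able to carry the stated modification
#' (contain A for m6A, C for m4C/m5C).
#'
#' @param pattern IUPAC string over A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N.
#' @param meth_offset 0-based index of the methylated base within `pattern`.
#' @param mod_type One of `"m6A"`, `"m4C"`, `"m5C"`, `"unknown"`.
#' @return An object of class `iupac_motif`.
#' @examples
#' iupac_motif("GANTC", 1, "m6A")   # HinfI-like site, methylated adenine
#' iupac_motif("GCWGC", 1, "m4C")
#' @export
iupac_motif <- function(pattern, meth_offset, mod_type = "unknown") {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) >= 1L)
  sets <- pattern_base_sets(pattern)
  meth_offset <- as.integer(meth_offset)
  if (is.na(meth_offset) || meth_offset < 0L || meth_offset >= nchar(pattern)) {
    stop("meth_offset must lie within the pattern (0-based)")
  }
  mod_type <- match.arg(mod_type, MOD_TYPES)
  central <- sets[[meth_offset + 1L]]
  if (mod_type == "m6A" && !"A" %in% central) {
    stop("m6A motif must allow A at the methylated offset")
  }
  if (mod_type %in% c("m4C", "m5C") && !"C" %in% central) {
    stop(mod_type, " motif must allow C at the methylated offset")
  }
  structure(list(pattern = pattern, meth_offset = meth_offset, mod_type = mod_type),
            class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(format_motif(x), " [", x$mod_type, "]\n", sep = "")
  invisible(x)
}

#' @rdname format_motif
#' @param x An `iupac_motif`.
#' @param ... Ignored.
#' @export
format.iupac_motif <- function(x, ...) format_motif(x)

#' Render / parse the motif text syntax
#'
#' The file syntax marks the methylated base with a preceding lowercase `m`,
#' e.g. `"GmANTC"` for GANTC methylated at offset 1.
#'
#' @param m An `iupac_motif`.
#' @return `format_motif()`: a string; `parse_motif()`: an `iupac_motif`.
#' @export
format_motif <- function(m) {
  p <- m$pattern
  paste0(substr(p, 1, m$meth_offset), "m", substr(p, m$meth_offset + 1L, nchar(p)))
}

#' @rdname format_motif
#' @param text Motif string with an `m` anchor.
#' @param mod_type Modification type to attach.
#' @export
parse_motif <- function(text, mod_type = "unknown") {
  pos <- regexpr("m", text, fixed = TRUE)
  if (pos < 1L) stop("motif text must carry an 'm' anchor before the methylated base")
  iupac_motif(sub("m", "", text, fixed = TRUE), as.integer(pos) - 1L, mod_type)
}

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

rc_pattern <- function(pattern) {
  chars <- rev(strsplit(pattern, "")[[1]])
  paste(unname(IUPAC_COMPLEMENT[chars]), collapse = "")
}

#' Reverse complement of a motif
#'
#' The pattern is reversed with IUPAC-complemented codes and the methylated
#' offset is mapped to `length - 1 - meth_offset` (i.e. onto the base that
#' pairs with the original methylated base). Modification type is preserved.
#' The operation is an involution.
#'
#' @param m An `iupac_motif`.
#' @return An `iupac_motif`.
#' @examples
#' motif_rc(iupac_motif("AGCNNNNNNCAT", 0, "m6A"))  # ATGNNNNNNGCT, offset 11
#' @export
motif_rc <- function(m) {
  stopifnot(inherits(m, "iupac_motif"))
  structure(list(pattern = rc_pattern(m$pattern),
                 meth_offset = nchar(m$pattern) - 1L - m$meth_offset,
                 mod_type = m$mod_type),
            class = "iupac_motif")
}

is_self_rc <- function(m) identical(rc_pattern(m$pattern), m$pattern)

# Match a degenerate pattern against one sequence; returns 0-based starts.
# Non-ACGT letters in the subject never match (windows containing them are
# discarded), per the occurrence contract.
match_starts <- function(pattern, seq) {
  if (nchar(seq) < nchar(pattern) || nchar(seq) == 0L) return(integer(0))
  subj <- Biostrings::DNAString(seq)
  hits <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
  starts <- IRanges::start(hits)
  if (length(starts) && grepl("[^ACGT]", seq)) {
    w <- nchar(pattern)
    keep <- !vapply(starts, function(s)
      grepl("[^ACGT]", substr(seq, s, s + w - 1L)), logical(1))
    starts <- starts[keep]
  }
  starts - 1L
}

#' Strand-specific motif occurrences in a sequence
#'
#' Counts forward-strand matches of the pattern and reverse-strand matches
#' (forward matches of the reverse complement). A self-reverse-complementary
#' motif therefore yields two entries per duplex site, one per strand.
#' Positions are 0-based forward-strand coordinates of the pattern start.
#'
#' @param m An `iupac_motif`.
#' @param seq Nucleotide string; non-ACGT characters never match.
#' @return `data.frame` with columns `position`, `strand`.
#' @export
motif_occurrences <- function(m, seq) {
  stopifnot(inherits(m, "iupac_motif"), is.character(seq), length(seq) == 1L)
  fwd <- match_starts(m$pattern, seq)
  rev_ <- match_starts(rc_pattern(m$pattern), seq)
  out <- data.frame(position = c(fwd, rev_),
                    strand = rep(c("+", "-"), c(length(fwd), length(rev_))),
                    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Forward-strand coordinates of the methylated base for each occurrence
#'
#' For a `+` occurrence starting at `p` the methylated base sits at
#' `p + meth_offset`; for a `-` occurrence (pattern read 5'->3' on the minus
#' strand) it sits at `p + length - 1 - meth_offset`.
#'
#' @inheritParams motif_occurrences
#' @return `data.frame` with columns `position` (methylated base, 0-based
#'   forward coordinates) and `strand`.
#' @export
motif_meth_positions <- function(m, seq) {
  occ <- motif_occurrences(m, seq)
  L <- nchar(m$pattern)
  occ$position <- ifelse(occ$strand == "+",
                         occ$position + m$meth_offset,
                         occ$position + L - 1L - m$meth_offset)
  occ
}

#' Position-wise base-set intersection of two motifs
#'
#' Aligns the two patterns so their methylated bases coincide and intersects
#' the expanded base sets position by position; positions covered by only one
#' motif are reported as overhangs.
#'
#' @param m1,m2 `iupac_motif` objects with defined methylated offsets.
#' @return `data.frame` with columns `rel` (position relative to the
#'   methylated base), `code1`, `code2` (NA on overhangs), `intersection`
#'   (bases in common, as a string), `empty` (conflict flag) and `overhang`.
#' @export
positionwise_intersection <- function(m1, m2) {
  stopifnot(inherits(m1, "iupac_motif"), inherits(m2, "iupac_motif"))
  s1 <- pattern_base_sets(m1$pattern)
  s2 <- pattern_base_sets(m2$pattern)
  r1 <- seq_along(s1) - 1L - m1$meth_offset
  r2 <- seq_along(s2) - 1L - m2$meth_offset
  rel <- sort(union(r1, r2))
  c1 <- strsplit(m1$pattern, "")[[1]][match(rel, r1)]
  c2 <- strsplit(m2$pattern, "")[[1]][match(rel, r2)]
  inter <- character(length(rel))
  for (i in seq_along(rel)) {
    a <- match(rel[i], r1); b <- match(rel[i], r2)
    inter[i] <- if (is.na(a) || is.na(b)) NA_character_ else
      paste(intersect(s1[[a]], s2[[b]]), collapse = "")
  }
  overhang <- is.na(c1) | is.na(c2)
  data.frame(rel = rel, code1 = c1, code2 = c2, intersection = inter,
             empty = !overhang & !nzchar(ifelse(is.na(inter), "x", inter)),
             overhang = overhang, stringsAsFactors = FALSE)
}

# zero-conflict end-to-end comparison of two pattern strings with at most
# `max_overhang` unaligned bases in total; tries every sliding offset that
# satisfies the overhang budget.
patterns_compatible <- function(p1, p2, max_overhang = 1L, max_conflicts = 0L) {
  s1 <- pattern_base_sets(p1); s2 <- pattern_base_sets(p2)
  L1 <- length(s1); L2 <- length(s2)
  for (d in -max_overhang:max_overhang) {
    # s1[i] aligned with s2[i + d]
    i_lo <- max(1L, 1L - d); i_hi <- min(L1, L2 - d)
    if (i_hi < i_lo) next
    overlap <- i_hi - i_lo + 1L
    if (L1 + L2 - 2L * overlap > max_overhang) next
    conflicts <- 0L
    for (i in i_lo:i_hi) {
      if (!length(intersect(s1[[i]], s2[[i + d]]))) conflicts <- conflicts + 1L
      if (conflicts > max_conflicts) break
    }
    if (conflicts <= max_conflicts) return(TRUE)
  }
  FALSE
}

same_mod_class <- function(t1, t2) {
  cls <- function(t) if (t == "m6A") "A" else if (t %in% c("m4C", "m5C")) "C" else "?"
  cls(t1) == cls(t2) && cls(t1) != "?"
}

#' Are two motifs duplex (reverse-complement) partners?
#'
#' True when the reverse complement of `m1` matches `m2` position by position
#' with no conflicting base set (at most one unaligned overhang base in
#' total), and both motifs carry the same modification class (both m6A, or
#' both cytosine modifications). Such pairs reflect double-strand methylation
#' of one duplex recognition site.
#'
#' @param m1,m2 `iupac_motif` objects.
#' @param max_overhang Total unaligned bases allowed between the two patterns.
#' @return Logical.
#' @export
rc_compatible <- function(m1, m2, max_overhang = 1L) {
  stopifnot(inherits(m1, "iupac_motif"), inherits(m2, "iupac_motif"))
  if (!same_mod_class(m1$mod_type, m2$mod_type)) return(FALSE)
  patterns_compatible(rc_pattern(m1$pattern), m2$pattern,
                      max_overhang = max_overhang, max_conflicts = 0L)
}

#' Are two motifs near-duplicates of one underlying motif?
#'
#' True when both motifs have the same modification type and, aligned at their
#' methylated bases, at most one position has an empty base-set intersection,
#' with at most one unaligned overhang base in total. This is the rule that
#' clusters incomplete detections of a single methylated motif (the
#' HCAGCTKC / GMAGCTKC / BGMAGCTGD style of trio) while keeping genuinely
#' different spacer motifs apart.
#'
#' @inheritParams rc_compatible
#' @param max_conflicts Conflicting aligned positions allowed.
#' @return Logical.
#' @export
similarity_mergeable <- function(m1, m2, max_conflicts = 1L, max_overhang = 1L) {
  stopifnot(inherits(m1, "iupac_motif"), inherits(m2, "iupac_motif"))
  if (m1$mod_type != m2$mod_type) return(FALSE)
  pw <- positionwise_intersection(m1, m2)
  sum(pw$empty) <= max_conflicts && sum(pw$overhang) <= max_overhang
}

#' Deduplicate motifs across genomes and group novel ones
#'
#' Deduplicates by exact pattern string across genomes, marks each distinct
#' motif as reference-known iff its pattern (or reverse complement) exactly
#' equals a reference pattern, then merges the remaining novel motifs by
#' single-linkage over reverse-complement compatibility and near-duplicate
#' similarity. Degenerate subsumption does not confer known status.
#'
#' @param motifs `data.frame` with columns `genome_id`, `pattern`,
#'   `meth_offset`, `mod_type` (one row per genome x motif).
#' @param reference Character vector of reference (known) patterns.
#' @return List with `motifs` (distinct motifs with `reference_known` and
#'   `group` id), `groups` (list of groups with members and kind),
#'   `n_distinct` and `n_novel_groups`.
#' @export
dedupe_and_group <- function(motifs, reference = character(0)) {
  stopifnot(is.data.frame(motifs),
            all(c("genome_id", "pattern", "meth_offset", "mod_type") %in% names(motifs)))
  if (!nrow(motifs)) stop("empty motif set")
  pats <- sort(unique(motifs$pattern))
  first <- motifs[match(pats, motifs$pattern), , drop = FALSE]
  objs <- Map(iupac_motif, first$pattern, first$meth_offset, first$mod_type)
  genomes <- vapply(pats, function(p)
    paste(sort(unique(motifs$genome_id[motifs$pattern == p])), collapse = ","), "")
  ref_rc <- vapply(reference, rc_pattern, "")
  known <- pats %in% reference | pats %in% ref_rc

  group <- rep(NA_integer_, length(pats))
  novel_idx <- which(!known)
  if (length(novel_idx)) {
    parent <- seq_along(novel_idx)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(novel_idx)) {
      for (b in seq_len(a - 1L)) {
        ma <- objs[[novel_idx[a]]]; mb <- objs[[novel_idx[b]]]
        if (rc_compatible(ma, mb) || similarity_mergeable(ma, mb)) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    roots <- vapply(seq_along(novel_idx), find, 1L)
    group[novel_idx] <- match(roots, sort(unique(roots)))
  }

  groups <- lapply(sort(unique(group[!is.na(group)])), function(g) {
    idx <- which(!is.na(group) & group == g)
    kind <- if (length(idx) == 1L) "single" else if (length(idx) == 2L &&
      rc_compatible(objs[[idx[1]]], objs[[idx[2]]])) "rc_pair" else "similarity_cluster"
    list(patterns = pats[idx], genomes = genomes[idx], kind = kind,
         reference_known = FALSE)
  })

  list(motifs = data.frame(pattern = pats,
                           meth_offset = first$meth_offset,
                           mod_type = first$mod_type,
                           genomes = unname(genomes),
                           reference_known = known,
                           group = group,
                           stringsAsFactors = FALSE),
       groups = groups,
       n_distinct = length(pats),
       n_novel_groups = length(groups))
}
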