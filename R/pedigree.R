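#' Construct and validate a pedigree
#'
#' A pedigree is a set of individuals with parent links and family labels.
#' Founders have both parents missing; non-founders must have both parents
#' present, in the same family, and the parent relation must be acyclic.
#' Individuals flagged `sampled = FALSE` are phantom connecting ancestors:
#' they participate in the kinship recursion but are excluded from all
#' matrices delivered to inference.
#'
#' On construction the records are reordered family-contiguously (families in
#' order of first appearance), within family topologically (parents before
#' children), ties broken by input order. The original ids are preserved.
#'
#' @param id character vector of individual ids, unique within the pedigree.
#' @param father,mother character vectors of parent ids; `NA`, `""` or `"0"`
#'   denote a missing parent.
#' @param sex integer codes: 1 = male, 2 = female, 0 = unknown. Carried
#'   through but unused by the autosomal kinship computation.
#' @param family character vector of family labels.
#' @param sampled logical; `FALSE` marks phantom connecting ancestors.
#' @return An object of class `pedigree`: a data frame with columns
#'   `id`, `father`, `mother`, `sex`, `family`, `sampled`, sorted as above.
#' @examples
#' ped <- pedigree(id = c("f", "m", "c1", "c2"),
#'                 father = c(NA, NA, "f", "f"),
#'                 mother = c(NA, NA, "m", "m"),
#'                 sex = c(1, 2, 1, 2), family = "fam1")
#' kinship(ped)
#' @export
pedigree <- function(id, father, mother, sex = 0L, family = "1",
                     sampled = TRUE) {
  id <- as.character(id)
  n <- length(id)
  father <- normalize_parent(rep_len(as.character(father), n))
  mother <- normalize_parent(rep_len(as.character(mother), n))
  sex <- rep_len(as.integer(sex), n)
  family <- rep_len(as.character(family), n)
  sampled <- rep_len(as.logical(sampled), n)

  dup <- id[duplicated(id)]
  if (length(dup) > 0L)
    stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "))
  one_parent <- xor(is.na(father), is.na(mother))
  if (any(one_parent))
    stop("individual(s) with exactly one parent recorded: ",
         paste(id[one_parent], collapse = ", "))

  idx <- match(father, id)
  bad <- !is.na(father) & is.na(idx)
  idxm <- match(mother, id)
  badm <- !is.na(mother) & is.na(idxm)
  if (any(bad | badm))
    stop("parent id not found in pedigree for individual(s): ",
         paste(id[bad | badm], collapse = ", "))
  cross <- (!is.na(idx) & family[idx] != family) |
    (!is.na(idxm) & family[idxm] != family)
  if (any(cross))
    stop("parent recorded in a different family for individual(s): ",
         paste(id[cross], collapse = ", "))

  ord <- pedigree_order(id, father, mother, family)
  ped <- data.frame(id = id[ord], father = father[ord], mother = mother[ord],
                    sex = sex[ord], family = family[ord],
                    sampled = sampled[ord], stringsAsFactors = FALSE)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  attr(ped, "sorted") <- TRUE
  ped
}

normalize_parent <- function(x) {
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

# Family-contiguous + topological (Kahn) ordering; ties broken by input order.
# Raises an error naming an individual on any ancestry cycle.
pedigree_order <- function(id, father, mother, family) {
  fam_levels <- unique(family)
  out <- integer(0)
  for (f in fam_levels) {
    members <- which(family == f)
    fid <- id[members]
    fa <- match(father[members], fid)  # NA for founders
    mo <- match(mother[members], fid)
    n <- length(members)
    indeg <- ifelse(is.na(fa), 0L, 1L) + ifelse(is.na(mo), 0L, 1L)
    placed <- logical(n)
    order_f <- integer(0)
    repeat {
      ready <- which(!placed & indeg == 0L)
      if (length(ready) == 0L) break
      nxt <- ready[1L]  # input order tie-break
      placed[nxt] <- TRUE
      order_f <- c(order_f, nxt)
      kids <- which(!placed & (!is.na(fa) & fa == nxt | !is.na(mo) & mo == nxt))
      indeg[kids] <- indeg[kids] -
        (ifelse(!is.na(fa[kids]) & fa[kids] == nxt, 1L, 0L) +
         ifelse(!is.na(mo[kids]) & mo[kids] == nxt, 1L, 0L))
    }
    if (any(!placed))
      stop("cyclic ancestry involving individual(s): ",
           paste(fid[!placed], collapse = ", "))
    out <- c(out, members[order_f])
  }
  out
}

#' Read a pedigree from a delimited text file
#'
#' Two dialects are supported. `"fam"` is the PLINK six-column FAM layout
#' (family id, individual id, father, mother, sex, phenotype) with no header,
#' whitespace- or comma-delimited. `"ped"` expects a header row with columns
#' named (case-insensitively) `fid`/`family`, `iid`/`id`, `father`/`pat`,
#' `mother`/`mat`, and optionally `sex`. A missing parent is encoded `"0"` or
#' an empty field in either dialect.
#'
#' @param path path to the pedigree file.
#' @param dialect `"fam"` or `"ped"`.
#' @param sampled optional character vector of sampled individual ids; ids
#'   absent from it are treated as phantom connecting ancestors. Default: all
#'   individuals sampled.
#' @return A validated [pedigree].
#' @export
read_pedigree <- function(path, dialect = c("fam", "ped"), sampled = NULL) {
  dialect <- match.arg(dialect)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  if (dialect == "fam") {
    tab <- read.table(path, header = FALSE, sep = sep,
                      colClasses = "character", strip.white = TRUE)
    if (ncol(tab) < 6L)
      stop("FAM dialect requires 6 columns, found ", ncol(tab))
    names(tab)[1:6] <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  } else {
    tab <- read.table(path, header = TRUE, sep = sep,
                      colClasses = "character", strip.white = TRUE)
    names(tab) <- tolower(names(tab))
    pick <- function(...) {
      cand <- c(...)
      hit <- cand[cand %in% names(tab)]
      if (length(hit) == 0L)
        stop("missing pedigree column; expected one of: ",
             paste(cand, collapse = ", "))
      hit[1L]
    }
    tab <- data.frame(fid = tab[[pick("fid", "family", "famid")]],
                      iid = tab[[pick("iid", "id", "individual")]],
                      pat = tab[[pick("father", "pat", "dadid")]],
                      mat = tab[[pick("mother", "mat", "momid")]],
                      sex = if ("sex" %in% names(tab)) tab[["sex"]] else "0",
                      stringsAsFactors = FALSE)
  }
  samp <- if (is.null(sampled)) TRUE else tab$iid %in% sampled
  pedigree(id = tab$iid, father = tab$pat, mother = tab$mat,
           sex = suppressWarnings(as.integer(tab$sex)),
           family = tab$fid, sampled = samp)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d sampled) in %d families\n",
              nrow(x), sum(x$sampled), length(unique(x$family))))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Per-family offset index
#'
#' Returns the 1-based index of the first sampled individual of each family
#' block, plus a terminal `N + 1`, in the pedigree's family-contiguous
#' ordering: block `i` spans `offsets[i] .. offsets[i+1] - 1`. This is the
#' `offset` vector used by the BUGS model and by all block-wise computations.
#'
#' @param ped a [pedigree].
#' @return An object of class `family_offsets`: a list with `offsets`
#'   (integer, length `n_fam + 1`), `n_fam`, `N`, and `families` (labels).
#' @export
family_offsets <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  fam <- ped$family[ped$sampled]
  if (length(fam) == 0L) stop("pedigree has no sampled individuals")
  runs <- rle(fam)
  if (anyDuplicated(runs$values))
    stop("family labels are not contiguous: ",
         paste(unique(runs$values[duplicated(runs$values)]), collapse = ", "))
  off <- cumsum(c(1L, runs$lengths))
  structure(list(offsets = as.integer(off), n_fam = length(runs$values),
                 N = length(fam), families = runs$values),
            class = "family_offsets")
}

#' @export
print.family_offsets <- function(x, ...) {
  cat(sprintf("family offsets: %d families, N = %d\n", x$n_fam, x$N))
  cat("offsets: ", paste(head(x$offsets, 12L), collapse = ", "),
      if (length(x$offsets) > 12L) ", ..." else "", "\n", sep = "")
  invisible(x)
}
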