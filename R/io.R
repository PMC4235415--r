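#' Write a pedigree as a PLINK-style FAM file
#'
#' Six whitespace-delimited columns, no header: family id, individual id,
#' father, mother, sex, phenotype. Missing parents are written `"0"`.
#' Phantom (unsampled) individuals are included — they are needed to
#' reconstruct the kinship — with phenotype `-9`.
#'
#' @param ped a [pedigree].
#' @param path output file.
#' @param phenotype optional numeric vector over sampled individuals,
#'   in pedigree order; default `-9` (missing) everywhere.
#' @return Invisibly, `path`.
#' @export
write_fam <- function(ped, path, phenotype = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  ph <- rep(-9, nrow(ped))
  if (!is.null(phenotype)) {
    stopifnot(length(phenotype) == sum(ped$sampled))
    ph[ped$sampled] <- phenotype
  }
  tab <- data.frame(fid = ped$family, iid = ped$id,
                    pat = ifelse(is.na(ped$father), "0", ped$father),
                    mat = ifelse(is.na(ped$mother), "0", ped$mother),
                    sex = ped$sex, pheno = ph)
  write.table(tab, path, quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a square matrix as TSV with id header row and column
#'
#' @param M matrix with dimnames.
#' @param path file path.
#' @return `write_matrix_tsv`: invisibly `path`; `read_matrix_tsv`: the
#'   matrix.
#' @export
write_matrix_tsv <- function(M, path) {
  stopifnot(is.matrix(M))
  if (is.null(rownames(M))) dimnames(M) <- list(seq_len(nrow(M)),
                                                seq_len(ncol(M)))
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  M <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(M) <- tab[[1L]]
  M
}

#' Read a phenotype/covariate table
#'
#' Delimited text with a header row; must contain an individual-id column
#' (`iid` or `id`). Rows are matched to the sampled individuals of the
#' pedigree by id and returned in pedigree order.
#'
#' @param path file path (tab-, comma- or whitespace-delimited; inferred).
#' @param ped a [pedigree] providing the target ordering.
#' @param trait name of the trait column.
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @return List with `y`, `X` (intercept column plus covariates) and `ids`.
#' @export
read_phenotypes <- function(path, ped, trait = "y", covariates = character()) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  idcol <- intersect(c("iid", "id"), names(tab))[1L]
  if (is.na(idcol)) stop("phenotype file needs an 'iid' or 'id' column")
  want <- ped$id[ped$sampled]
  hit <- match(want, as.character(tab[[idcol]]))
  if (anyNA(hit))
    stop("phenotype file is missing sampled individual(s): ",
         paste(head(want[is.na(hit)], 5L), collapse = ", "))
  cols <- tolower(c(trait, covariates))
  miss <- setdiff(cols, names(tab))
  if (length(miss) > 0L)
    stop("phenotype file is missing column(s): ", paste(miss, collapse = ", "))
  y <- tab[[tolower(trait)]][hit]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(tab[hit, tolower(covariates), drop = FALSE]))
  colnames(X) <- c("(Intercept)", covariates)
  list(y = y, X = X, ids = want)
}
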