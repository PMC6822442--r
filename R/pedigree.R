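#' Construct a pedigree
#'
#' Builds a validated, topologically ordered pedigree from animal, sire and
#' dam identifiers. Unknown parents are coded as \code{NA}, \code{0} or
#' \code{""}. The returned object stores parents as integer row pointers, so
#' downstream relationship-matrix algebra never touches identifiers again.
#'
#' @param id vector of unique animal identifiers, ordered so that every parent
#'   appears before its offspring.
#' @param sire,dam parent identifiers (same length as \code{id}); unknown
#'   parents as \code{NA}, \code{0} or \code{""}.
#' @param genotyped logical vector flagging genotyped animals (recycled).
#' @param sex optional vector (\code{"M"}/\code{"F"}); used by the simulator
#'   and the PED writer, ignored by the relationship algebra.
#'
#' @return An object of class \code{"pedigree"}: a list with \code{id},
#'   \code{sire} and \code{dam} (integer indices, \code{NA} = unknown),
#'   \code{genotyped} and optional \code{sex}.
#' @examples
#' ped <- pedigree(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
#'                 dam = c(NA, NA, "d"))
#' a_matrix(ped)
#' @export
pedigree <- function(id, sire, dam, genotyped = FALSE, sex = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (n == 0L) stop("empty pedigree")
  if (anyDuplicated(id)) stop("duplicated animal ids in pedigree")
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0" | x == ""] <- NA_character_
    x
  }
  sire_i <- match(norm(sire), id)
  dam_i <- match(norm(dam), id)
  known_s <- !is.na(norm(sire))
  known_d <- !is.na(norm(dam))
  if (any(known_s & is.na(sire_i))) stop("sire id not found in pedigree")
  if (any(known_d & is.na(dam_i))) stop("dam id not found in pedigree")
  seq_n <- seq_len(n)
  bad <- which(!is.na(sire_i) & sire_i >= seq_n | !is.na(dam_i) & dam_i >= seq_n)
  if (length(bad) > 0L)
    stop("pedigree is not topologically ordered (parent at or after offspring) ",
         "for animals: ", paste(utils::head(id[bad], 5L), collapse = ", "))
  structure(
    list(id = id,
         sire = as.integer(sire_i),
         dam = as.integer(dam_i),
         genotyped = rep_len(as.logical(genotyped), n),
         sex = if (!is.null(sex)) rep_len(as.character(sex), n)),
    class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  n <- length(x$id)
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat("Pedigree with", n, "animals (", nf, "founders,",
      sum(x$genotyped), "genotyped )\n")
  invisible(x)
}

#' Number of animals in a pedigree
#' @param ped a \code{\link{pedigree}}.
#' @return integer count.
#' @export
n_animals <- function(ped) length(ped$id)

#' Read / write a three-column pedigree file
#'
#' Plain CSV with columns \code{id,sire,dam} (and optionally
#' \code{genotyped}, \code{sex}); \code{0} codes an unknown parent.
#'
#' @param file path to a CSV file.
#' @return \code{read_pedigree} returns a \code{\link{pedigree}}.
#' @export
read_pedigree <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  pedigree(df$id, df$sire, df$dam,
           genotyped = if ("genotyped" %in% names(df))
             as.logical(as.integer(df$genotyped)) else FALSE,
           sex = if ("sex" %in% names(df)) df$sex)
}

#' @rdname read_pedigree
#' @param ped a \code{\link{pedigree}} to write.
#' @return \code{write_pedigree} returns \code{file}, invisibly.
#' @export
write_pedigree <- function(ped, file) {
  code <- function(i) ifelse(is.na(i), "0", ped$id[i])
  df <- data.frame(id = ped$id, sire = code(ped$sire), dam = code(ped$dam),
                   genotyped = as.integer(ped$genotyped))
  if (!is.null(ped$sex)) df$sex <- ped$sex
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
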