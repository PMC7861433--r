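#' Drug identifier record
#'
#' Bundles the coding-system identifiers and dosing constants needed to
#' standardise prescription quantities for a single active ingredient: the
#' WHO ATC code, the BNF chemical-substance code used in NHS prescribing
#' extracts, the WHO defined daily dose (DDD, in mg) and the licensed unit
#' strengths.
#'
#' @param name Generic drug name.
#' @param atc_code 7-character ATC code (e.g. `"B01AF03"`).
#' @param bnf_code 9-character BNF chemical code (e.g. `"0208020AA"`).
#' @param ddd_mg WHO defined daily dose in mg; must be positive.
#' @param strengths_mg Numeric vector of licensed strengths in mg per unit.
#' @return An object of class `drug_identifier`.
#' @export
drug_identifier <- function(name, atc_code, bnf_code, ddd_mg, strengths_mg) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(ddd_mg) || length(ddd_mg) != 1L || ddd_mg <= 0) {
    stop("ddd_mg must be a single positive number", call. = FALSE)
  }
  if (length(strengths_mg) < 1L || any(strengths_mg <= 0)) {
    stop("strengths_mg must be positive", call. = FALSE)
  }
  structure(
    list(name = name, atc_code = toupper(atc_code),
         bnf_code = toupper(bnf_code), ddd_mg = as.numeric(ddd_mg),
         strengths_mg = as.numeric(strengths_mg)),
    class = "drug_identifier"
  )
}

#' @method print drug_identifier
#' @export
print.drug_identifier <- function(x, ...) {
  cat(sprintf("<drug_identifier> %s  ATC %s  BNF %s  DDD %g mg  strengths: %s mg\n",
              x$name, x$atc_code, x$bnf_code, x$ddd_mg,
              paste(x$strengths_mg, collapse = "/")))
  invisible(x)
}

#' Load the drug registry
#'
#' Reads a plain-text registry table (columns `NAME`, `ATC`, `BNF`, `DDD_MG`,
#' `STRENGTHS_MG` with semicolon-separated strengths). The packaged default
#' registry carries the four licensed NOACs; additional drugs can be supplied
#' via a user file without code changes.
#'
#' @param path Registry file; defaults to the packaged NOAC registry.
#' @return A named list of [drug_identifier()] records (names are generic
#'   drug names).
#' @export
load_registry <- function(path = system.file("extdata", "noac_registry.tsv",
                                             package = "ddmap")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("NAME", "ATC", "BNF", "DDD_MG", "STRENGTHS_MG")
  if (!all(needed %in% names(tab))) {
    stop("registry file must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    drug_identifier(tab$NAME[i], tab$ATC[i], tab$BNF[i], tab$DDD_MG[i],
                    as.numeric(strsplit(tab$STRENGTHS_MG[i], ";")[[1]]))
  })
  names(out) <- tab$NAME
  out
}

#' Look up a drug by ATC or BNF code
#'
#' Case-insensitive exact match against either coding system.
#'
#' @param code ATC or BNF code string.
#' @param registry Registry list from [load_registry()].
#' @return The matching [drug_identifier()].
#' @export
lookup_identifier <- function(code, registry = load_registry()) {
  code <- toupper(trimws(code))
  for (d in registry) {
    if (identical(d$atc_code, code) || identical(d$bnf_code, code)) return(d)
  }
  stop(sprintf("no registry entry for code '%s'", code), call. = FALSE)
}

#' DDD-equivalent of a batch of prescription items
#'
#' Converts dispensed quantities at mixed strengths into a single unit-free
#' total of WHO defined daily doses:
#' \deqn{\mathrm{DDD} = \sum_k q_k\, s_k / \mathrm{DDD}_{mg}}
#' where \eqn{q_k} is the dispensed unit count and \eqn{s_k} the strength in
#' mg per unit. For example 100 units at 30 mg plus 200 units at 60 mg of a
#' drug with DDD 60 mg is (100*30 + 200*60)/60 = 250 DDDs.
#'
#' The result is additive over any partition of the item list and linear in
#' the quantities.
#'
#' @param quantity Numeric vector of dispensed unit counts (non-negative).
#' @param strength_mg Numeric vector of strengths (mg per unit), recycled
#'   against `quantity`.
#' @param ddd_mg The drug's WHO DDD in mg (positive scalar).
#' @return Total DDD equivalent (non-negative scalar; 0 for empty input).
#' @export
ddd_equivalent <- function(quantity, strength_mg, ddd_mg) {
  if (!is.numeric(ddd_mg) || length(ddd_mg) != 1L || !is.finite(ddd_mg) ||
      ddd_mg <= 0) {
    stop("ddd_mg must be a single positive number", call. = FALSE)
  }
  if (length(quantity) == 0L) return(0)
  if (any(!is.finite(quantity)) || any(quantity < 0)) {
    stop("quantities must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(strength_mg)) || any(strength_mg <= 0)) {
    stop("strengths must be finite and positive", call. = FALSE)
  }
  sum(quantity * strength_mg) / ddd_mg
}

#' DDD rate per 1,000 population
#'
#' The study's primary outcome scale: total DDD equivalents divided by the
#' population served and multiplied by 1,000.
#'
#' @param total_ddd Non-negative DDD total.
#' @param population Positive person count.
#' @return DDD per 1,000 population.
#' @export
rate_per_1000 <- function(total_ddd, population) {
  if (any(!is.finite(population)) || any(population <= 0)) {
    stop("population must be positive", call. = FALSE)
  }
  if (any(total_ddd < 0)) stop("total_ddd must be non-negative", call. = FALSE)
  total_ddd / population * 1000
}

# Round half-up to integer (0.5 always rounds away from zero towards +Inf);
# used when a real-valued DDD total becomes the Poisson count y.
round_half_up <- function(x) floor(x + 0.5)
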