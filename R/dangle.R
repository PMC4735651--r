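# Motif-sum duplex free-energy model and the saturating
# multinucleotide-dangle length correction.

#' Saturating dangle-length model
#'
#' Long dangles destabilize the adjacent duplex relative to a
#' single-nucleotide dangle: the first dangle base contributes a partial
#' terminal stack, while every further base adds electrostatic repulsion
#' with diminishing reach. The correction is parameterised as
#' `A * (1 - exp(-(L - 1)/lambda))` — zero at L = 1 by definition,
#' monotonically approaching the plateau penalty `A` (the measured
#' long-dangle asymptote is +0.56 kcal mol^-1, reached by roughly 8 nt).
#' The empirical length table this curve summarises is not reproduced here;
#' the parametric form stands in for it.
#'
#' @param A plateau penalty in kcal mol^-1 (>= 0).
#' @param lambda length scale in nucleotides (> 0); the default 2.0 puts
#'   97% of the plateau at L = 8.
#' @param A_se,lambda_se,base_dg,base_dg_se optional fit metadata filled in
#'   by [fit_length_model()].
#' @return Object of class `dangle_length_model`; `saturation_length` is
#'   the smallest integer L whose correction reaches 95% of `A`.
#' @export
dangle_length_model <- function(A = 0.56, lambda = 2,
                                A_se = NA_real_, lambda_se = NA_real_,
                                base_dg = NA_real_, base_dg_se = NA_real_) {
  if (!is.finite(A) || A < 0) stop("plateau penalty 'A' must be >= 0")
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be > 0")
  structure(
    list(A = A, lambda = lambda,
         saturation_length = 1L + as.integer(ceiling(-lambda * log(0.05))),
         A_se = A_se, lambda_se = lambda_se,
         base_dg = base_dg, base_dg_se = base_dg_se),
    class = "dangle_length_model"
  )
}

#' @export
print.dangle_length_model <- function(x, ...) {
  cat(sprintf("<dangle_length_model> A = %.3f kcal/mol", x$A))
  if (!is.na(x$A_se)) cat(sprintf(" (se %.3f)", x$A_se))
  cat(sprintf(", lambda = %.2f nt", x$lambda))
  if (!is.na(x$lambda_se)) cat(sprintf(" (se %.2f)", x$lambda_se))
  cat(sprintf(", saturation at ~%d nt\n", x$saturation_length))
  invisible(x)
}

#' Destabilization of a length-L dangle relative to a single-nucleotide dangle
#'
#' @param L dangle length(s) in nucleotides; integer >= 1.
#' @param model a [dangle_length_model()].
#' @return Correction(s) in kcal mol^-1: 0 at L = 1, non-decreasing,
#'   approaching `A`.
#' @export
length_correction <- function(L, model = dangle_length_model()) {
  stopifnot(inherits(model, "dangle_length_model"))
  if (any(L < 1) || any(L != round(L))) {
    stop("dangle length 'L' must be an integer >= 1, got: ",
         deparse(L[L < 1 | L != round(L)][1L]))
  }
  model$A * (1 - exp(-(L - 1) / model$lambda))
}

# ---- motif tables -------------------------------------------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(seq) {
  paste(rev(COMPLEMENT[strsplit(toupper(seq), "")[[1L]]]), collapse = "")
}

# Canonical lookup key for each motif class.
motif_key <- function(motif_class, side = "", dangle_base = "",
                      closing_pair = "") {
  switch(motif_class,
         initiation = "init",
         stack = paste0("stack:", closing_pair),
         dangle = paste0("dangle:", side, ":", dangle_base, ":", closing_pair),
         fluorophore = paste0("fluor:", side, ":", dangle_base, ":",
                              closing_pair),
         stop("unknown motif_class: ", motif_class))
}

#' Read a motif parameter table
#'
#' Tab-separated table with columns `motif_class` (initiation, stack,
#' dangle, fluorophore), `side` (`5p`/`3p`, empty for stacks/initiation),
#' `dangle_base` (the dangle nucleotide, or the fluorophore name for
#' fluorophore rows), `closing_pair` (the adjacent duplex base for dangles
#' and fluorophores; the top-strand dinucleotide, 5'->3', for stacks),
#' `temperature_C`, `buffer`, `dG_kcal_mol` and `sd`. Parameter values are
#' supplied by the user; the package ships only a small synthetic toy table
#' (`system.file("extdata", "toy_motifs_synthetic.tsv", package =
#' "nativedg")`).
#'
#' @param path TSV path.
#' @return Object of class `motif_table`: the parsed data.frame plus an
#'   `entries` lookup (named dG vector keyed by canonical motif keys).
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("motif_class", "side", "dangle_base", "closing_pair",
            "temperature_C", "buffer", "dG_kcal_mol", "sd")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("motif table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  keys <- mapply(motif_key, df$motif_class, df$side, df$dangle_base,
                 df$closing_pair, USE.NAMES = FALSE)
  if (anyDuplicated(keys)) {
    stop("duplicate motif entries: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  if (any(!is.finite(df$dG_kcal_mol))) stop("motif dG values must be finite")
  motif_table(stats::setNames(df$dG_kcal_mol, keys), table = df)
}

#' @rdname read_motif_table
#' @param entries named numeric vector of motif dGs keyed by canonical
#'   keys (`"init"`, `"stack:<dinuc>"`, `"dangle:<side>:<base>:<closing>"`,
#'   `"fluor:<side>:<name>:<closing>"`).
#' @param table optional originating data.frame.
#' @export
motif_table <- function(entries, table = NULL) {
  if (is.null(names(entries)) || anyDuplicated(names(entries))) {
    stop("'entries' must be uniquely named")
  }
  structure(list(entries = entries, table = table), class = "motif_table")
}

# ---- duplex prediction --------------------------------------------------

#' Predict a duplex formation free energy as a sum of motif contributions
#'
#' The standard local model: the complex is dissected into non-overlapping
#' motifs (helix initiation, nearest-neighbour base stacks, terminal
#' dangles, terminal fluorophores) whose tabulated dGs add. The bottom
#' strand must be fully paired; the top strand may overhang at either end.
#' 5' and 3' dangle entries are keyed separately — no 3'/5' symmetry is
#' assumed (3' dangles stack more weakly). A dangle longer than 1 nt
#' contributes its single-nucleotide entry (for the base adjacent to the
#' duplex) plus the saturating [length_correction()]; the bases past the
#' first must be a homopolymer (secondary-structure-free), matching the
#' model's scope.
#'
#' @param seq_top top strand, 5'->3' (A/C/G/T).
#' @param seq_bottom bottom strand, 5'->3'; must be the exact complement of
#'   a contiguous region of the top strand.
#' @param table a [motif_table()] (or named dG vector).
#' @param length_model a [dangle_length_model()]; required whenever a
#'   dangle exceeds 1 nt.
#' @param fluor5,fluor3 optional fluorophore names attached at the top
#'   strand's 5'/3' terminus.
#' @return Predicted formation dG in kcal mol^-1 (sum of table entries plus
#'   any length correction).
#' @export
duplex_delta_g <- function(seq_top, seq_bottom, table, length_model = NULL,
                           fluor5 = NULL, fluor3 = NULL) {
  entries <- if (inherits(table, "motif_table")) table$entries else table
  if (is.null(names(entries))) stop("'table' must carry named motif entries")
  top <- toupper(seq_top)
  paired <- revcomp(seq_bottom)
  hits <- gregexpr(paired, top, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) {
    stop("the bottom strand's complement does not occur in the top strand; ",
         "strands are not complementary over a contiguous duplex region")
  }
  if (length(hits) > 1L) {
    stop("ambiguous duplex register: the paired region occurs ",
         length(hits), " times in the top strand")
  }
  pos <- hits[1L]
  d5 <- substr(top, 1L, pos - 1L)
  d3 <- substr(top, pos + nchar(paired), nchar(top))
  keys <- "init"
  nd <- nchar(paired)
  if (nd < 2L) stop("duplex region must span at least one base stack (2 bp)")
  for (i in seq_len(nd - 1L)) {
    keys <- c(keys, motif_key("stack", closing_pair = substr(paired, i, i + 1L)))
  }
  correction <- 0
  add_dangle <- function(dangle_seq, side, closing) {
    L <- nchar(dangle_seq)
    adjacent <- if (side == "5p") substr(dangle_seq, L, L)
                else substr(dangle_seq, 1L, 1L)
    rest <- if (side == "5p") substr(dangle_seq, 1L, L - 1L)
            else substr(dangle_seq, 2L, L)
    if (L > 1L) {
      if (is.null(length_model)) {
        stop("a ", L, " nt ", side, " dangle needs a dangle_length_model ",
             "for the multinucleotide correction")
      }
      rest_bases <- unique(strsplit(rest, "")[[1L]])
      if (length(rest_bases) > 1L) {
        stop("only homopolymer multinucleotide dangles are supported; ",
             side, " dangle continues with ",
             paste(rest_bases, collapse = "/"))
      }
      correction <<- correction + length_correction(L, length_model)
    }
    motif_key("dangle", side, adjacent, closing)
  }
  if (nchar(d5)) keys <- c(keys, add_dangle(d5, "5p", substr(paired, 1L, 1L)))
  if (nchar(d3)) keys <- c(keys, add_dangle(d3, "3p", substr(paired, nd, nd)))
  if (!is.null(fluor5)) {
    keys <- c(keys, motif_key("fluorophore", "5p", fluor5,
                              substr(top, 1L, 1L)))
  }
  if (!is.null(fluor3)) {
    keys <- c(keys, motif_key("fluorophore", "3p", fluor3,
                              substr(top, nchar(top), nchar(top))))
  }
  absent <- setdiff(keys, names(entries))
  if (length(absent)) {
    stop("motif table is missing entries: ", paste(absent, collapse = ", "))
  }
  sum(entries[keys]) + correction
}

#' Fit the saturating dangle-length model to a measured length series
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt,
#' [minpack.lm::nlsLM()]) of `dG(L) = base + A (1 - exp(-(L - 1)/lambda))`
#' with weights `1/sd^2`. Standard errors come from the Jacobian at the
#' optimum.
#'
#' @param data data.frame with columns `L` (dangle length, nt), `dg`
#'   (kcal mol^-1) and `sd` (> 0). At least 3 distinct lengths including
#'   the L = 1 reference.
#' @param start optional named start list (`base`, `A`, `lambda`).
#' @return A [dangle_length_model()] carrying fitted values, standard
#'   errors, the baseline `base_dg` and the underlying `nls` fit as
#'   attribute `"fit"`.
#' @export
fit_length_model <- function(data, start = NULL) {
  need <- c("L", "dg", "sd")
  if (!all(need %in% names(data))) stop("'data' needs columns L, dg, sd")
  if (length(unique(data$L)) < 3L) stop("need >= 3 distinct dangle lengths")
  if (!1 %in% data$L) stop("the length series must include the L = 1 reference")
  if (any(data$sd <= 0)) stop("per-point sds must be > 0")
  if (is.null(start)) {
    start <- list(base = mean(data$dg[data$L == 1]),
                  A = max(max(data$dg) - min(data$dg), 0.05),
                  lambda = 2)
  }
  predict_dg <- function(p) p[1L] + p[2L] * (1 - exp(-(data$L - 1) / p[3L]))
  resid_z <- function(p) (data$dg - predict_dg(p)) / data$sd
  fit <- minpack.lm::nls.lm(
    par = unlist(start)[c("base", "A", "lambda")],
    lower = c(base = -Inf, A = 0, lambda = 1e-2),
    fn = resid_z,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0L, 9L)) {
    stop("length-model fit did not converge from start ",
         paste(sprintf("%s=%.3g", names(start), unlist(start)),
               collapse = ", "), "; last iterate ",
         paste(sprintf("%s=%.3g", names(fit$par), fit$par), collapse = ", "))
  }
  p <- fit$par
  # parameter covariance from the weighted Jacobian at the optimum, scaled
  # by the residual variance; pseudo-inverse when the plateau sits on its
  # zero bound (lambda is then unidentified)
  dof <- max(nrow(data) - 3L, 1L)
  sigma2 <- fit$deviance / dof
  covm <- tryCatch(solve(fit$hessian) * sigma2, error = function(e) {
    sv <- svd(fit$hessian)
    pos <- sv$d > max(sv$d) * 1e-10
    ginv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    ginv * sigma2
  })
  se <- sqrt(pmax(diag(covm), 0))
  model <- dangle_length_model(A = p[["A"]], lambda = p[["lambda"]],
                               A_se = se[2L], lambda_se = se[3L],
                               base_dg = p[["base"]], base_dg_se = se[1L])
  attr(model, "fit") <- fit
  model
}
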