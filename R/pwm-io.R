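#' Write a PWM library as JASPAR-like text
#'
#' One record per motif: a `>name` header then four rows
#' `A [ f1 f2 ... ]`, ..., `T [ ... ]` of per-position frequencies.
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm_library <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$name),
      vapply(seq_len(4L), function(r) {
        paste0(DNA_BASES[r], " [ ",
               paste(formatC(p$mat[r, ], format = "g", digits = 10),
                     collapse = " "),
               " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM library
#'
#' Accepts two text dialects: JASPAR-like (`>name` header, then four rows
#' `A [ ... ]` ... `T [ ... ]`) and a bare 4-row tab/space-separated block
#' per motif under the same `>name` header.  Counts are auto-normalized to
#' frequencies per column.
#'
#' @param path Input path.
#' @param pseudocount,weights Settings applied to every motif; see [pwm()].
#' @return Named list of [pwm()] objects.
#' @export
read_pwm_library <- function(path, pseudocount = 0.001,
                             weights = c("ic", "uniform")) {
  weights <- match.arg(weights)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop_bad_arg("no '>' motif headers found")
  ends <- c(starts[-1L] - 1L, length(lines))
  pwms <- lapply(seq_along(starts), function(k) {
    name <- sub("^>\\s*", "", lines[starts[k]])
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 4L) {
      stop_bad_arg("motif '", name, "': expected 4 base rows, got ",
                   length(body))
    }
    rows <- lapply(body, function(ln) {
      ln <- sub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[][]", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    base_labels <- toupper(substr(body, 1L, 1L))
    mat <- do.call(rbind, rows)
    if (all(sort(base_labels) == DNA_BASES)) {
      mat <- mat[match(DNA_BASES, base_labels), , drop = FALSE]
    }
    pwm(name, mat, pseudocount = pseudocount, weights = weights)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "name")
  pwms
}

# One Dirichlet(alpha, ..., alpha) draw per column.
.rdirichlet_col <- function(n_col, alpha) {
  g <- matrix(rgamma(4L * n_col, shape = alpha), 4L, n_col)
  sweep(g, 2L, colSums(g), "/")
}

#' Generate a synthetic PWM library
#'
#' Motif columns are Dirichlet draws: `ic_profile = "high"` uses a sparse
#' Dirichlet (concentration 0.2) giving peaked, informative columns;
#' `"low"` uses concentration 5 (near-uniform columns); `"mixed"` picks a
#' profile per motif.  High-information motifs routinely contain
#' zero-or-near-zero base frequencies, the substrate for planting
#' allele-disrupting variants.
#'
#' @param n_pwms Number of motifs.
#' @param length_range Length-2 integer interval of motif lengths (min 4).
#' @param ic_profile `"low"`, `"high"` or `"mixed"`.
#' @param seed Integer seed.
#' @param pseudocount,weights Settings stored on each motif; see [pwm()].
#' @return Named list of [pwm()] objects (`PWM001`, `PWM002`, ...).
#' @export
generate_pwm_library <- function(n_pwms, length_range = c(8L, 16L),
                                 ic_profile = c("mixed", "low", "high"),
                                 seed, pseudocount = 0.001,
                                 weights = c("ic", "uniform")) {
  ic_profile <- match.arg(ic_profile)
  weights <- match.arg(weights)
  if (length_range[1] < 4L) stop_bad_arg("motif length must be >= 4")
  with_seed(seed, {
    pwms <- lapply(seq_len(n_pwms), function(k) {
      L <- sample(length_range[1]:length_range[2], 1L)
      prof <- if (ic_profile == "mixed") {
        sample(c("low", "high"), 1L)
      } else {
        ic_profile
      }
      alpha <- if (prof == "high") 0.2 else 5
      mat <- .rdirichlet_col(L, alpha)
      pwm(sprintf("PWM%03d", k), mat, pseudocount = pseudocount,
          weights = weights)
    })
    names(pwms) <- vapply(pwms, `[[`, character(1), "name")
    pwms
  })
}
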