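#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

GROUP_LEVELS <- c("centenarian", "offspring", "control")

as_group_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), GROUP_LEVELS)
  if (length(bad) > 0) {
    stop2("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  factor(as.character(x), levels = GROUP_LEVELS)
}

# format numerics with 6 significant digits for deterministic TSV output
format_signif <- function(x, digits = 6) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, digits), digits = digits,
                                          format = "g"))
}
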