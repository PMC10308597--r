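# internal helpers shared across modules

# parallel combination of impedances; Inf branches drop out
zpar <- function(...) {
  zs <- list(...)
  y <- 0 + 0i
  for (z in zs) {
    if (all(is.infinite(Mod(z)))) next
    y <- y + 1 / z
  }
  1 / y
}

# run code with a local RNG state so simulation is a pure function of its seed
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_domain(name, " must be a single finite number")
  if (!allow_inf && is.infinite(x))
    stop_domain(name, " must be finite")
  if (strict_lower && x <= lower)
    stop_domain(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_domain(name, " must be >= ", lower)
  if (x > upper)
    stop_domain(name, " must be <= ", upper)
  invisible(x)
}

# compact label for a carrier frequency, e.g. 45e3 -> "45k", 2e6 -> "2M"
freq_label <- function(f) {
  vapply(f, function(fi) {
    if (fi >= 1e6) paste0(format(fi / 1e6, trim = TRUE, drop0trailing = TRUE), "M")
    else if (fi >= 1e3) paste0(format(fi / 1e3, trim = TRUE, drop0trailing = TRUE), "k")
    else format(fi, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}

# inverse of freq_label
label_freq <- function(lab) {
  mult <- ifelse(grepl("M$", lab), 1e6, ifelse(grepl("k$", lab), 1e3, 1))
  as.numeric(sub("[kM]$", "", lab)) * mult
}
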