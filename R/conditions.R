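# Classed conditions so callers can distinguish format corruption from
# caller mistakes from calibration problems.

stop_edf <- function(class, msg, ...) {
  extra <- list(...)
  cond <- errorCondition(msg, class = c(class, "edf2csf_error"), call = sys.call(-1))
  for (nm in names(extra)) cond[[nm]] <- extra[[nm]]
  stop(cond)
}

format_error      <- function(msg, ...) stop_edf("edf_format_error", msg, ...)
truncation_error  <- function(msg, ...) stop_edf(c("edf_truncation_error", "edf_format_error"), msg, ...)
calibration_error <- function(msg, ...) stop_edf("edf_calibration_error", msg, ...)
usage_error       <- function(msg, ...) stop_edf("edf2csf_usage_error", msg, ...)
config_error      <- function(msg, ...) stop_edf(c("edf2csf_config_error", "edf2csf_usage_error"), msg, ...)
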