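`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (ddof = 0)
.pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
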