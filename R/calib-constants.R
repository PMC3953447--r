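## Generated by tools/calibrate-reference.R -- do not edit by hand.
## Latent covariances of the cohort generator fitted to the published
## per-sex adjusted correlation matrices (see calibrate_cohort_model).
.calibration_constants <-
list(male = list(Lambda = structure(c(0x1.ecd70a3d708a8p+4, 0x1.4f84209f06497p+6, 
0x1.d1ff8b6eb2a4ep+5, 0x1.08d8494d4de45p+4, 0x1.89ebffd19e7fp+4, 
0x1.16d69fc8cedb9p+1, 0x1.08c3410d66e35p+1, 0x1.2a83bf91373c8p+1, 
0x1.4f84209f06497p+6, 0x1.13985b2e432c6p+8, 0x1.4c40788183217p+7, 
0x1.34262443d8f6dp+5, 0x1.1ccf706fb8f8cp+6, 0x1.bd34b1bac13bp+2, 
0x1.8cbf9530294d1p+2, 0x1.e0dd865d26afbp+2, 0x1.d1ff8b6eb2a4ep+5, 
0x1.4c40788183217p+7, 0x1.29b2ad7b1799ap+7, 0x1.a94ac0b32941ap+4, 
0x1.9ea9a8dc8921fp+5, 0x1.05b0540ba360fp+2, 0x1.1cb9c55628986p+2, 
0x1.15ab9ce1db986p+2, 0x1.08d8494d4de45p+4, 0x1.34262443d8f6dp+5, 
0x1.a94ac0b32941ap+4, 0x1.66fe35154d879p+4, 0x1.567396bbfe663p+3, 
0x1.e28d6152b0c9fp-1, 0x1.23901e4bd43e3p-1, 0x1.7848515ca7ba5p-1, 
0x1.89ebffd19e7fp+4, 0x1.1ccf706fb8f8cp+6, 0x1.9ea9a8dc8921fp+5, 
0x1.567396bbfe663p+3, 0x1.cd7e4af78660ep+4, 0x1.9df0160efaee5p+0, 
0x1.df02ab720d267p+0, 0x1.d67b75497eb73p+0, 0x1.16d69fc8cedb9p+1, 
0x1.bd34b1bac13bp+2, 0x1.05b0540ba360fp+2, 0x1.e28d6152b0c9fp-1, 
0x1.9df0160efaee5p+0, 0x1.f0240ba7f466fp-3, 0x1.2bb1450fc5a9p-3, 
0x1.ea2981f1a1e3dp-3, 0x1.08c3410d66e35p+1, 0x1.8cbf9530294d1p+2, 
0x1.1cb9c55628986p+2, 0x1.23901e4bd43e3p-1, 0x1.df02ab720d267p+0, 
0x1.2bb1450fc5a9p-3, 0x1.59e143a29bd37p-3, 0x1.520315bf0fa4p-3, 
0x1.2a83bf91373c8p+1, 0x1.e0dd865d26afbp+2, 0x1.15ab9ce1db986p+2, 
0x1.7848515ca7ba5p-1, 0x1.d67b75497eb73p+0, 0x1.ea2981f1a1e3dp-3, 
0x1.520315bf0fa4p-3, 0x1.6597b11a214ep-2), dim = c(8L, 8L), dimnames = list(
    c("bmi", "wc", "hc", "smt", "rest", "vat", "sat", "cat"), 
    c("bmi", "wc", "hc", "smt", "rest", "vat", "sat", "cat"))), 
    mL = c(VAT = 0x1.4f9d5e0265b71p+2, SAT = 0x1.ef63d4d9210c8p+3, 
    CAT = 0x1.e97b765338aep-2), noise_var = 0x1.eb851eb851eb8p-6), 
    female = list(Lambda = structure(c(0x1.3880000003e9bp+5, 
    0x1.6846290173cbdp+6, 0x1.64422ba09fbd1p+6, 0x1.b20b8df12b22dp+3, 
    0x1.8fa2fb381655fp+4, 0x1.23de5f7054db7p+1, 0x1.eba0e86b2e5c5p+0, 
    0x1.a6cae8e5e55cdp+1, 0x1.6846290173cbdp+6, 0x1.05abc53fe6df8p+8, 
    0x1.a50369be22f23p+7, 0x1.00b4621c86448p+5, 0x1.c08368ba54d9ap+5, 
    0x1.8898721f64b42p+2, 0x1.2030eacc53a19p+2, 0x1.23a595d74128bp+3, 
    0x1.64422ba09fbd1p+6, 0x1.a50369be22f23p+7, 0x1.d4587043ae3e8p+7, 
    0x1.af9f9307d6342p+4, 0x1.e05b290b9999fp+5, 0x1.4518c5c5f989p+2, 
    0x1.2df82a0f55f36p+2, 0x1.db67dd76e897dp+2, 0x1.b20b8df12b22dp+3, 
    0x1.00b4621c86448p+5, 0x1.af9f9307d6342p+4, 0x1.3d74495be3d02p+3, 
    0x1.bbf8cd8d907b3p+2, 0x1.7ed727c660181p-1, 0x1.0a617dcdca08p-1, 
    0x1.10c0e8af307b1p+0, 0x1.8fa2fb381655fp+4, 0x1.c08368ba54d9ap+5, 
    0x1.e05b290b9999fp+5, 0x1.bbf8cd8d907b3p+2, 0x1.38837c6565472p+4, 
    0x1.681bdecc04e94p+0, 0x1.4bb7b9bca3c36p+0, 0x1.01d84a02f93bbp+1, 
    0x1.23de5f7054db7p+1, 0x1.8898721f64b42p+2, 0x1.4518c5c5f989p+2, 
    0x1.7ed727c660181p-1, 0x1.681bdecc04e94p+0, 0x1.9f380e70def2dp-3, 
    0x1.ad150d0480c1fp-4, 0x1.12fda88bc6a02p-2, 0x1.eba0e86b2e5c5p+0, 
    0x1.2030eacc53a19p+2, 0x1.2df82a0f55f36p+2, 0x1.0a617dcdca08p-1, 
    0x1.4bb7b9bca3c36p+0, 0x1.ad150d0480c1fp-4, 0x1.a21bdaca4ed8cp-4, 
    0x1.3271430825259p-3, 0x1.a6cae8e5e55cdp+1, 0x1.23a595d74128bp+3, 
    0x1.db67dd76e897dp+2, 0x1.10c0e8af307b1p+0, 0x1.01d84a02f93bbp+1, 
    0x1.12fda88bc6a02p-2, 0x1.3271430825259p-3, 0x1.1ef4a48da7882p-1
    ), dim = c(8L, 8L), dimnames = list(c("bmi", "wc", "hc", 
    "smt", "rest", "vat", "sat", "cat"), c("bmi", "wc", "hc", 
    "smt", "rest", "vat", "sat", "cat"))), mL = c(VAT = 0x1.7ad98e912722p+1, 
    SAT = 0x1.535a814afd6ap+4, CAT = 0x1.27c0d60a46443p-2), noise_var = 0x1.eb851eb851eb8p-6))
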