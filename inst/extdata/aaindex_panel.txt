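H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
      3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H KLEP840101
D Net charge (Klein et al., 1984)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
        0       1       0      -1       0       0      -1       0       0       0
        0       1       0       0       0       0       0       0       0       0
//
H BHAR880101
D Average flexibility indices (Bhaskaran-Ponnuswamy, 1988)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.357   0.529   0.463   0.511   0.346   0.493   0.497   0.544   0.323   0.462
    0.365   0.466   0.295   0.314   0.509   0.507   0.444   0.305    0.42   0.386
//
H CHOC760101
D Residue accessible surface area in tripeptide (Chothia, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      115     225     160     150     135     180     190      75     195     175
      170     200     185     210     145     115     140     255     230     155
//
H CHOP780201
D Normalized frequency of alpha-helix (Chou-Fasman, 1978b)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.42    0.98    0.67    1.01     0.7    1.11    1.51    0.57       1    1.08
     1.21    1.16    1.45    1.13    0.57    0.77    0.83    1.08    0.69    1.06
//
H CHOP780202
D Normalized frequency of beta-sheet (Chou-Fasman, 1978b)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.83    0.93    0.89    0.54    1.19     1.1    0.37    0.75    0.87     1.6
      1.3    0.74    1.05    1.38    0.55    0.75    1.19    1.37    1.47     1.7
//
H DAYM780201
D Relative mutability (Dayhoff et al., 1978b)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      100      65     134     106      20      93     102      49      66      96
       40      56      94      41      56     120      97      18      41      74
//
H RACS820112
D Average relative fractional occurrence in ER(i-1) (Rackovsky-Scheraga, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.99    1.19    1.15    1.18    2.32    1.52    1.36     1.4    1.06    0.81
     1.26    0.91       1    1.25       0     1.5    1.18    1.33    1.09    1.01
//
H ISOY800103
D Normalized relative frequency of bend (Isogai et al., 1980)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.78    1.06    1.56     1.5     0.6    0.78    0.97    1.73    0.83     0.4
     0.57    1.01     0.3    0.67    1.55    1.19    1.09    0.74    1.14    0.44
//
H JOND750102
D pK (-COOH) (Jones, 1975)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     2.34    1.18    2.02    2.01    1.65    2.17    2.19    2.34    1.82    2.36
     2.36    2.18    2.28    1.83    1.99    2.21     2.1    2.38     2.2    2.32
//
H ROBB760107
D Information measure for extended without H-bond (Robson-Suzuki, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
        0     1.1      -2    -2.6     5.4     2.4     3.1    -3.4     0.8    -0.1
     -3.7    -3.1    -2.1     0.7     7.4     1.3       0    -3.4     4.8     2.7
//
H BULH740101
D Transfer free energy to surface (Bull-Breese, 1974)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     -0.2   -0.12    0.08    -0.2   -0.45    0.16    -0.3       0   -0.12   -2.26
    -2.46   -0.35   -1.47   -2.33   -0.98   -0.39   -0.52   -2.01   -2.24   -1.56
//
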