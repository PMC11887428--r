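# Bundled reference table 1: experimental nitrogen drift-tube CCS values for
# glycan ions determined by the stepped-field and the calibrated single-field
# method, with the printed absolute and percent differences between the two.
# Values transcribed as printed; single_sd is the reported spread where one
# was given.  Units: A^2.
analyte,mode,stepped_A2,single_A2,single_sd,abs_delta_printed,pct_delta_printed
Cellobiose,neg,167.86,179.70,NA,11.84,6.81
Glucosamine,pos,135.59,139.75,2.3,4.16,3.02
Glucuronate,neg,134.23,131.70,NA,2.53,1.90
Inositol,neg,144.27,129.96,1.9,14.32,10.44
Isomaltose,neg,180.77,171.96,NA,8.81,5.00
Lactose,neg,170.23,176.90,NA,6.67,3.84
Maltose,neg,205.90,180.10,NA,25.80,13.37
Palatinose,neg,172.60,177.90,NA,5.30,3.02
Raffinose,neg,197.59,197.30,NA,0.29,0.15
Stachyose,neg,226.67,222.61,2,4.06,1.81
Sucrose,neg,168.47,168.20,NA,0.27,0.16
Xylitol,neg,127.92,124.1,1.7,3.82,3.03
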