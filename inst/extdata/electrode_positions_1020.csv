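"name","x","y","z"
"Fp1",-0.308832495270115,0.950488686437586,-0.0345506413744723
"Fp2",0.308832495270115,0.950488686437586,-0.0345506413744723
"F3",-0.544677635608984,0.67262086344177,0.50090662536071
"F4",0.544677635608984,0.67262086344177,0.50090662536071
"C3",-0.720309024887907,4.41062070862963e-17,0.693653305812805
"C4",0.720309024887907,4.41062070862963e-17,0.693653305812805
"P3",-0.544677635608985,-0.67262086344177,0.50090662536071
"P4",0.544677635608985,-0.67262086344177,0.50090662536071
"O1",-0.308832495270115,-0.950488686437586,-0.0345506413744723
"O2",0.308832495270115,-0.950488686437586,-0.0345506413744723
"F7",-0.808533969447601,0.587434314140669,-0.0345506413744723
"F8",0.808533969447601,0.587434314140669,-0.0345506413744723
"T3",-0.999402948354973,6.11957810880673e-17,-0.0345506413744723
"T4",0.999402948354973,6.11957810880673e-17,-0.0345506413744723
"T5",-0.808533969447601,-0.587434314140669,-0.0345506413744723
"T6",0.808533969447601,-0.587434314140669,-0.0345506413744723
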