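population,j,age_lo,age_hi,tau,incidence,mortality
caucasian-1983-87,1,0,19,20,0,0
caucasian-1983-87,2,20,24,25,1,49.3
caucasian-1983-87,3,25,29,30,7.6,53.1
caucasian-1983-87,4,30,34,35,26.6,62.5
caucasian-1983-87,5,35,39,40,66.1,82.5
caucasian-1983-87,6,40,44,45,126.5,130.7
caucasian-1983-87,7,45,49,50,186.6,218.1
caucasian-1983-87,8,50,54,55,221.1,365.5
caucasian-1983-87,9,55,59,60,272.1,585.2
caucasian-1983-87,10,60,64,65,334.8,943.9
caucasian-1983-87,11,65,69,70,392.3,1502.8
caucasian-1983-87,12,70,74,75,417.8,2383.9
caucasian-1983-87,13,75,79,80,443.9,3883.2
caucasian-1983-87,14,80,84,85,442.1,6682.8
caucasian-1983-87,15,85,89,90,410.9,14490.8
sg-overall,1,0,19,20,0.3,11.7
sg-overall,2,20,24,25,1.9,14.3
sg-overall,3,25,29,30,8.1,14.2
sg-overall,4,30,34,35,24.8,19.8
sg-overall,5,35,39,40,57.6,32.6
sg-overall,6,40,44,45,118.7,58.5
sg-overall,7,45,49,50,162.6,106.2
sg-overall,8,50,54,55,187,182.1
sg-overall,9,55,59,60,204.3,319.1
sg-overall,10,60,64,65,199.1,565.9
sg-overall,11,65,69,70,193.9,989.5
sg-overall,12,70,74,75,166.5,1798.6
sg-overall,13,75,79,80,179,3285.3
sg-overall,14,80,84,85,189.8,5681
sg-overall,15,85,89,90,166.2,11425.5
sg-chinese,1,0,19,20,0.2,10.5
sg-chinese,2,20,24,25,1.8,11.9
sg-chinese,3,25,29,30,7,12.5
sg-chinese,4,30,34,35,25.5,16.8
sg-chinese,5,35,39,40,60.3,29.4
sg-chinese,6,40,44,45,121.5,51.6
sg-chinese,7,45,49,50,169.1,95.1
sg-chinese,8,50,54,55,193.6,165.1
sg-chinese,9,55,59,60,211,271.1
sg-chinese,10,60,64,65,202.1,489.6
sg-chinese,11,65,69,70,199.8,856.5
sg-chinese,12,70,74,75,161.3,1624.3
sg-chinese,13,75,79,80,180.9,3001.6
sg-chinese,14,80,84,85,191.4,5388.2
sg-chinese,15,85,89,90,164.5,11352.1
sg-malay,1,0,19,20,0.5,17.4
sg-malay,2,20,24,25,1.1,25.7
sg-malay,3,25,29,30,15.9,22.5
sg-malay,4,30,34,35,27.7,47
sg-malay,5,35,39,40,60,53.9
sg-malay,6,40,44,45,123.7,98.6
sg-malay,7,45,49,50,145.1,175.1
sg-malay,8,50,54,55,158.4,297.5
sg-malay,9,55,59,60,167,617.7
sg-malay,10,60,64,65,209.3,1093
sg-malay,11,65,69,70,131.9,2040.3
sg-malay,12,70,74,75,199.1,3034.6
sg-malay,13,75,79,80,128.6,5678.6
sg-malay,14,80,84,85,188.4,8681.2
sg-malay,15,85,89,90,117.6,13323.5
sg-indian,1,0,19,20,0.5,11
sg-indian,2,20,24,25,2.2,12.9
sg-indian,3,25,29,30,4.9,19.7
sg-indian,4,30,34,35,5.9,14.8
sg-indian,5,35,39,40,31.6,34.8
sg-indian,6,40,44,45,87.9,60.7
sg-indian,7,45,49,50,128.4,111.9
sg-indian,8,50,54,55,147.2,212.6
sg-indian,9,55,59,60,181.5,445.9
sg-indian,10,60,64,65,157.6,853.3
sg-indian,11,65,69,70,219.5,1158.5
sg-indian,12,70,74,75,152.5,1932.2
sg-indian,13,75,79,80,197.2,3662
sg-indian,14,80,84,85,125,6093.8
sg-indian,15,85,89,90,375,11000
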